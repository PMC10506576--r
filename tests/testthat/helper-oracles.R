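# Independent brute-force oracles used to pin expected values.

# Exact two-sided signed-rank p-value by literal enumeration of all 2^n sign
# assignments over the mid-ranks of |d| (zeros already removed by caller).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 14)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Exact McNemar p by binomial-tail enumeration.
oracle_mcnemar_exact_p <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  k <- min(b, c)
  min(1, 2 * sum(choose(n, 0:k)) / 2^n)
}

# A cohort config with all condition effects switched off (null simulator).
null_config <- function(n_young = 19L, n_old = 20L) {
  sim_config(n_young = n_young, n_old = n_old,
             beta_lowcut = 0, beta_series = 0)
}
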