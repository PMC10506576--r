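#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on the paired differences `x - y`. Zero
#' differences are discarded (the convention of the reference R
#' implementation, relevant here because Shift Index data are zero-rich);
#' tied absolute differences receive mid-ranks.
#'
#' Modes:
#' * `"exact"` — the exact null distribution of the positive-rank sum over
#'   all `2^n` sign assignments, computed by dynamic programming over the
#'   (doubled, hence integral) mid-ranks. Valid with ties.
#' * `"approx"` — normal approximation with continuity correction and the
#'   tie-corrected variance, matching `stats::wilcox.test(..., correct =
#'   TRUE)`.
#' * `"auto"` — exact when fewer than 50 non-zero differences, no ties among
#'   them and no zeros were discarded; otherwise approximate (the operative
#'   path for heavily tied SI data).
#'
#' @param x,y Paired numeric samples of equal length.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @param comparison Optional label carried into the result.
#'
#' @return An object of class `paired_test` with a [tidy()] method:
#'   `statistic` (positive-rank sum W+), `p_value`, `n_effective` (non-zero
#'   differences), `mode` (`"exact"`, `"approx"` or `"degenerate"`).
#'
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3), c(0, 0, 0)) # W+ = 6, exact p = 0.25
#' @export
wilcoxon_signed_rank <- function(x, y, mode = c("auto", "exact", "approx"),
                                 comparison = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(length(x) == length(y), length(x) >= 1L)
  d <- x - y
  d <- d[is.finite(d)]
  zeros <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(new_paired_test(comparison, "wilcoxon", 0, 1, 0L, "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  has_ties <- anyDuplicated(r) > 0L

  use_exact <- switch(mode,
    exact = TRUE,
    approx = FALSE,
    auto = n < 50L && !has_ties && zeros == 0L
  )

  if (use_exact) {
    p <- exact_signed_rank_p(r, w)
    return(new_paired_test(comparison, "wilcoxon", w, p, n, "exact"))
  }

  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- w - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
  new_paired_test(comparison, "wilcoxon", w, p, n, "approx")
}

# Exact two-sided p-value of the positive-rank sum by convolution over the
# doubled mid-ranks (integers even when ranks tie at .5).
exact_signed_rank_p <- function(ranks, w) {
  r2 <- as.integer(round(2 * ranks))
  counts <- 1
  for (ri in r2) {
    shifted <- c(rep(0, ri), counts)
    counts <- c(counts, rep(0, ri)) + shifted
  }
  total <- 2^length(r2)
  w2 <- round(2 * w)
  idx <- seq_along(counts) - 1L  # achievable doubled sums 0..sum(r2)
  p_le <- sum(counts[idx <= w2 + 1e-9]) / total
  p_ge <- sum(counts[idx >= w2 - 1e-9]) / total
  min(1, 2 * min(p_le, p_ge))
}

#' McNemar test for paired binary outcomes
#'
#' Tests marginal homogeneity from the discordant-pair counts `b` and `c`
#' (pairs where the two members of a matched pair disagree). The default is
#' the continuity-corrected chi-square statistic
#' `(|b - c| - 1)^2 / (b + c)` on 1 degree of freedom; `exact = TRUE` gives
#' the exact binomial version, `p = min(1, 2 * P(Bin(b + c, 1/2) <= min(b,
#' c)))`.
#'
#' @param b,c Discordant-pair counts (non-negative integers).
#' @param exact Use the exact binomial variant.
#' @param comparison Optional label carried into the result.
#'
#' @return A `paired_test` object; `statistic` is the chi-square statistic
#'   (or `min(b, c)` in exact mode), `n_effective` is `b + c`.
#'
#' @examples
#' mcnemar_test(1, 5)               # chi-square (|1-5|-1)^2/6 = 1.5
#' mcnemar_test(0, 5, exact = TRUE) # p = 2 * 0.5^5 = 0.0625
#' @export
mcnemar_test <- function(b, c, exact = FALSE, comparison = NA_character_) {
  stopifnot(length(b) == 1L, length(c) == 1L, b >= 0, c >= 0)
  n <- b + c
  if (n == 0L) {
    return(new_paired_test(comparison, "mcnemar", 0, 1, 0L, "degenerate"))
  }
  if (exact) {
    p <- min(1, 2 * pbinom(min(b, c), n, 0.5))
    return(new_paired_test(comparison, "mcnemar", min(b, c), p,
                           as.integer(n), "exact"))
  }
  stat <- (abs(b - c) - 1)^2 / n
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  new_paired_test(comparison, "mcnemar", stat, p, as.integer(n), "approx")
}

new_paired_test <- function(comparison, method, statistic, p_value,
                            n_effective, mode) {
  structure(
    list(comparison = comparison, method = method,
         statistic = as.numeric(statistic), p_value = p_value,
         n_effective = as.integer(n_effective), mode = mode),
    class = "paired_test"
  )
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf(
    "<paired_test> %s%s: statistic = %g, p = %.4g (n_eff = %d, %s)\n",
    x$method,
    if (is.na(x$comparison)) "" else paste0(" [", x$comparison, "]"),
    x$statistic, x$p_value, x$n_effective, x$mode
  ))
  invisible(x)
}

#' @rdname wilcoxon_signed_rank
#' @param x A `paired_test` (for `tidy`).
#' @param ... Unused.
#' @export
tidy.paired_test <- function(x, ...) {
  tibble::tibble(
    comparison = x$comparison, method = x$method, statistic = x$statistic,
    p_value = x$p_value, n_effective = x$n_effective, mode = x$mode
  )
}
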