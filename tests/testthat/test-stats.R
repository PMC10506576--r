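test_that("signed-rank test reproduces hand-enumerable cases", {
  # d = (1, 2, 3): all signs positive, W+ = 6, p = 2 * (1/8)
  res <- wilcoxon_signed_rank(c(1, 2, 3), c(0, 0, 0))
  expect_equal(res$statistic, 6)
  expect_equal(res$p_value, 0.25)
  expect_equal(res$mode, "exact")
  expect_equal(res$n_effective, 3L)

  # no information: identical samples
  deg <- wilcoxon_signed_rank(c(1, 1, 0), c(1, 1, 0))
  expect_equal(deg$mode, "degenerate")
  expect_equal(deg$p_value, 1)
  expect_equal(deg$statistic, 0)

  td <- tidy(res)
  expect_named(td, c("comparison", "method", "statistic", "p_value",
                     "n_effective", "mode"))
})

test_that("exact signed-rank p matches brute-force sign enumeration", {
  set.seed(101)
  checked <- 0L
  for (i in 1:200) {
    n <- sample(3:12, 1)
    x <- sample(c(-1, 0, 1), n, replace = TRUE)
    y <- sample(c(-1, 0, 1), n, replace = TRUE)
    d <- (x - y)[x != y]
    if (length(d) == 0) {
      expect_equal(wilcoxon_signed_rank(x, y)$p_value, 1)
      next
    }
    res <- wilcoxon_signed_rank(x, y, mode = "exact")
    expect_equal(res$p_value, oracle_signed_rank_p(d))
    checked <- checked + 1L
  }
  expect_gt(checked, 150L)
})

test_that("signed-rank agrees with the reference implementation", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    x <- rnorm(n)           # continuous: no ties, no zeros
    y <- rnorm(n)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    res <- wilcoxon_signed_rank(x, y)
    expect_equal(res$mode, "exact")
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value)
  }
  for (i in 1:25) {
    n <- sample(10:40, 1)
    x <- sample(c(-1, 0, 1), n, replace = TRUE)  # tied, zero-rich SI data
    y <- sample(c(-1, 0, 1), n, replace = TRUE)
    if (all(x == y)) next
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
    )
    res <- wilcoxon_signed_rank(x, y, mode = "approx")
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value)
  }
})

test_that("McNemar statistic and exact variant follow the definitions", {
  res <- mcnemar_test(1, 5)
  expect_equal(res$statistic, 1.5) # (|1 - 5| - 1)^2 / 6
  expect_equal(res$p_value, pchisq(1.5, 1, lower.tail = FALSE))
  expect_equal(res$n_effective, 6L)

  # symmetry in (b, c)
  expect_equal(mcnemar_test(7, 2)$statistic, mcnemar_test(2, 7)$statistic)
  expect_equal(mcnemar_test(7, 2)$p_value, mcnemar_test(2, 7)$p_value)

  # agreement with the reference implementation
  ref <- stats::mcnemar.test(matrix(c(10, 1, 5, 10), 2), correct = TRUE)
  expect_equal(mcnemar_test(1, 5)$statistic, unname(ref$statistic))
  expect_equal(mcnemar_test(1, 5)$p_value, ref$p.value)

  # exact binomial variant against tail enumeration
  expect_equal(mcnemar_test(0, 5, exact = TRUE)$p_value, 0.0625)
  for (b in 0:6) for (cc in 0:6) {
    expect_equal(mcnemar_test(b, cc, exact = TRUE)$p_value,
                 oracle_mcnemar_exact_p(b, cc))
  }

  expect_equal(mcnemar_test(0, 0)$p_value, 1)
  expect_equal(mcnemar_test(0, 0)$mode, "degenerate")

  # p decreases as the discordant counts diverge at fixed b + c
  # (non-strict for the corrected statistic: |b - c| of 0 and 2 coincide)
  ps <- sapply(0:5, function(b) mcnemar_test(b, 10 - b)$p_value)
  expect_true(all(diff(ps) >= 0))
  ps_exact <- sapply(0:4, function(b) mcnemar_test(b, 10 - b, exact = TRUE)$p_value)
  expect_true(all(diff(ps_exact) > 0))
})
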