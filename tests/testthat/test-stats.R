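test_that("Mann-Whitney exact path matches hand-derived cases", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_true(r$exact)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1) # 2/20 labelings as extreme
  expect_equal(mann_whitney(c(1, 2), c(1, 2))$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney equals full enumeration for all n1 + n2 <= 8", {
  set.seed(2024)
  for (n1 in 1:7) {
    for (n2 in 1:(8 - n1)) {
      x <- rnorm(n1)
      y <- rnorm(n2)
      r <- mann_whitney(x, y)
      expect_true(r$exact)
      expect_equal(r$p_value, oracle_mw_p(x, y), tolerance = 1e-12)
      expect_equal(r$statistic, oracle_mw_u(x, y))
      # independent cross-check against the base-R implementation
      expect_equal(r$p_value,
                   suppressWarnings(stats::wilcox.test(x, y, exact = TRUE)$p.value),
                   tolerance = 1e-12)
    }
  }
})

test_that("Mann-Whitney approximation is sane for larger samples", {
  set.seed(7)
  x <- rnorm(30); y <- rnorm(30, 1)
  r <- mann_whitney(x, y)
  expect_false(r$exact)
  ref <- stats::wilcox.test(x, y, correct = TRUE, exact = FALSE)$p.value
  expect_equal(r$p_value, ref, tolerance = 1e-10)
  # with heavy ties
  x2 <- rep(1:3, 10); y2 <- rep(2:4, 10)
  ref2 <- stats::wilcox.test(x2, y2, correct = TRUE, exact = FALSE)$p.value
  expect_equal(mann_whitney(x2, y2)$p_value, ref2, tolerance = 1e-10)
})

test_that("Wilcoxon signed-rank exact path matches enumeration", {
  r <- wilcoxon_signed_rank(2:7, 1:6)
  expect_true(r$exact)
  expect_equal(r$p_value, 2 * (1 / 2^6)) # all-positive differences, n = 6
  expect_warning(r0 <- wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_equal(r0$p_value, 1)

  set.seed(31)
  for (k in 1:6) {
    x <- rnorm(8)
    y <- rnorm(8)
    r <- wilcoxon_signed_rank(x, y)
    expect_true(r$exact)
    expect_equal(r$p_value, oracle_wsr_p(x, y), tolerance = 1e-12)
    expect_equal(r$p_value,
                 stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon normal approximation matches base R for n > 15", {
  set.seed(5)
  x <- rnorm(25); y <- rnorm(25, 0.5)
  r <- wilcoxon_signed_rank(x, y)
  expect_false(r$exact)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(r$p_value, ref, tolerance = 1e-10)
})

test_that("type-I error of the two-group test is near nominal", {
  set.seed(1234)
  rej <- vapply(1:2000, function(i) {
    mann_whitney(rnorm(10), rnorm(10))$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("BH adjustment reproduces the hand-worked case and its laws", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(11)
  p <- runif(40)^2
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_equal(adj, stats::p.adjust(p, "BH"))
  # invariance under permutation of test order
  perm <- sample(40)
  expect_equal(bh_adjust(p[perm]), adj[perm])
  # rank order preserved
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  # NAs pass through and shrink the family
  p2 <- c(0.01, NA, 0.04)
  expect_equal(bh_adjust(p2), c(0.02, NA, 0.04))
})

test_that("Spearman matrix recovers monotone relationships and adjusts p", {
  d <- data.frame(up = 1:8, down = 8:1, noisy = c(3, 1, 4, 1, 5, 9, 2, 6))
  r <- spearman_matrix(d)
  expect_equal(r$r["up", "down"], -1)
  expect_equal(unname(diag(r$r)), rep(1, 3))
  expect_equal(r$r, t(r$r))
  expect_true(all(r$p_adj >= r$p_raw, na.rm = TRUE))
  # cross-check one pair against base R
  ref <- stats::cor.test(d$up, d$noisy, method = "spearman", exact = FALSE)
  expect_equal(r$r["up", "noisy"], unname(ref$estimate))
  expect_equal(r$p_raw["up", "noisy"], ref$p.value, tolerance = 1e-10)
  # BH over the upper triangle only
  up <- r$p_raw[upper.tri(r$p_raw)]
  expect_equal(r$p_adj[upper.tri(r$p_adj)], stats::p.adjust(up, "BH"))
})

test_that("constant variables are excluded from the correlation family", {
  d <- data.frame(a = 1:6, b = c(2, 1, 4, 3, 6, 5), flat = rep(2, 6))
  r <- spearman_matrix(d)
  expect_true(is.na(r$r["a", "flat"]))
  expect_true(is.na(r$p_adj["a", "flat"]))
  expect_false(is.na(r$p_adj["a", "b"]))
})

test_that("Grubbs flags the planted outlier and respects its bounds", {
  g <- grubbs(c(10, 10.5, 9.5, 10.2, 9.8, 30))
  expect_equal(g$outliers, 6L)
  expect_gt(g$G[1], g$critical[1])
  # published critical value for n = 6, alpha = 0.05 is 1.887
  expect_equal(grubbs_critical(6, 0.05), 1.887, tolerance = 0.001)
  expect_length(grubbs(c(1, 2, 3))$outliers, 0)
  expect_error(grubbs(c(1, 2)), "at least 3")
  # G for n = 4 can never exceed (n-1)/sqrt(n) = 1.5
  set.seed(88)
  for (k in 1:50) {
    v <- rnorm(4, sd = sample(c(0.1, 1, 50), 1))
    expect_lte(max(abs(v - mean(v)) / sd(v)), 1.5 + 1e-12)
  }
  # iterated mode peels off successive extremes
  gi <- grubbs(c(rep(10, 8) + rnorm(8, 0, 0.1), 25, 40), iterate = TRUE)
  expect_true(all(c(9, 10) %in% gi$outliers))
})

test_that("delta-delta-Ct fold changes follow the worked cases", {
  expect_equal(as.numeric(ddct_fold_change(24, 20, 24, 20)), 1)
  expect_equal(as.numeric(ddct_fold_change(25, 20, 24, 20)), 0.5)
  expect_equal(as.numeric(ddct_fold_change(22, 20, 24, 20)), 4)
  # duplicate wells averaged on the Ct scale first
  expect_equal(
    as.numeric(ddct_fold_change(c(24.5, 25.5), c(19, 21), 24, 20)), 0.5
  )
  expect_error(ddct_fold_change(NA, 20, 24, 20), "finite")
})

test_that("significance stars follow the figure-legend convention", {
  expect_identical(
    significance_stars(c(0.2, 0.04, 0.009, 0.0009, 0.00009, NA)),
    c("ns", "*", "**", "***", "****", NA)
  )
})
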