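# Shared statistical primitives against brute-force oracles and closed forms.

test_that("rank-sum p-values match full enumeration for small tie-free samples", {
  set.seed(11)
  for (m in 1:5) for (n in 1:5) {
    x <- sample(100, m)
    y <- sample(100, n) + 0.5  # offset avoids ties with x
    got <- wilcoxon_rank_sum(x, y)
    expect_equal(got$p_value, oracle_wilcoxon_p(x, y), tolerance = 1e-10,
                 info = sprintf("m=%d n=%d", m, n))
  }
  expect_equal(wilcoxon_rank_sum(1:3, 4:6)$p_value, 0.1, tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(1, 2)$p_value, 1.0, tolerance = 1e-12)
})

test_that("rank-sum handles degenerate and tied inputs", {
  r <- wilcoxon_rank_sum(rep(5, 4), rep(5, 4))
  expect_equal(r$p_value, 1)
  expect_identical(r$direction, 0L)
  # ties force the corrected normal approximation, p stays valid
  r2 <- wilcoxon_rank_sum(c(1, 1, 2, 3), c(2, 2, 3, 4))
  expect_true(r2$p_value > 0 && r2$p_value <= 1)
  expect_identical(r2$direction, -1L)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "nonempty")
})

test_that("rank-sum direction follows the rank-biserial sign", {
  expect_identical(wilcoxon_rank_sum(c(10, 11, 12), c(1, 2, 3))$direction, 1L)
  expect_identical(wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))$direction, -1L)
})

test_that("spearman rho matches the d^2 formula and handles monotone transforms", {
  expect_equal(spearman_correlation(1:5, c(2, 1, 4, 3, 5))$rho, 0.8, tolerance = 1e-12)
  expect_equal(spearman_correlation(1:7, 1:7)$rho, 1)
  expect_equal(spearman_correlation(1:7, 7:1)$rho, -1)
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(9); y <- rnorm(9)
    expect_equal(spearman_correlation(x, y)$rho, oracle_spearman_rho(x, y),
                 tolerance = 1e-10)
    # invariance under strictly monotone transforms of either vector
    expect_equal(spearman_correlation(exp(x), y)$rho,
                 spearman_correlation(x, atan(y))$rho, tolerance = 1e-12)
  }
})

test_that("exact spearman permutation p matches brute-force enumeration", {
  set.seed(31)
  for (n in c(4, 5, 6, 7)) {
    x <- rnorm(n); y <- rnorm(n)
    got <- spearman_correlation(x, y, exact = TRUE)
    expect_equal(got$p_value, oracle_spearman_perm_p(x, y), tolerance = 1e-10)
  }
})

test_that("constant input flags the spearman result rather than erroring", {
  r <- spearman_correlation(rep(1, 5), 1:5)
  expect_true(is.na(r$rho))
  expect_match(r$method_note, "constant")
})

test_that("BH adjustment matches the step-up recursion and is order-invariant", {
  expect_equal(adjust_pvalues(c(.01, .02, .03, .04), "BH"), rep(.04, 4))
  expect_equal(adjust_pvalues(0.5, "BH"), 0.5)
  set.seed(41)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    adj <- adjust_pvalues(p, "BH")
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(adjust_pvalues(p[perm], "BH"), adj[perm], tolerance = 1e-12)
    expect_true(all(adjust_pvalues(p, "bonferroni") >= p))
  }
  expect_equal(adjust_pvalues(c(0.3, 0.0004), "bonferroni"), c(0.6, 0.0008))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("chi-square test reproduces hand computations and the Yates default", {
  # perfect independence
  r0 <- contingency_chi_square(matrix(5, 2, 2), continuity_correction = FALSE)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # hand Sum (O-E)^2/E for the diagonal table
  r1 <- contingency_chi_square(matrix(c(10, 0, 0, 10), 2), continuity_correction = FALSE)
  expect_equal(r1$statistic, 20, tolerance = 1e-12)
  # Yates on by default for 2x2
  r2 <- contingency_chi_square(matrix(c(10, 0, 0, 10), 2))
  expect_lt(r2$statistic, 20)
  expect_error(contingency_chi_square(matrix(c(0, 0, 1, 2), 2)), "margins")
  expect_error(contingency_chi_square(matrix(1:2, 2, 1)), "2x2")
})

test_that("kruskal-wallis matches the hand rank formula and degenerates to p = 1", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  # H = 12/(N(N+1)) * sum n_g (rbar_g - (N+1)/2)^2, no ties
  rb <- c(mean(c(1, 2)), mean(c(3, 4)), mean(c(5, 6)))
  H <- 12 / (6 * 7) * sum(2 * (rb - 3.5)^2)
  r <- kruskal_wallis(g)
  expect_equal(r$statistic, H, tolerance = 1e-12)
  expect_equal(r$p_value, stats::pchisq(H, df = 2, lower.tail = FALSE), tolerance = 1e-12)
  r2 <- kruskal_wallis(list(rep(2, 3), rep(2, 5)))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "nonempty")
})

test_that("least squares recovers noiseless coefficients and flags collinearity", {
  x <- seq(0, 1, length.out = 12)
  X <- cbind(intercept = 1, x = x)
  f <- fit_linear_model(X, 2 + 3 * x)
  expect_equal(unname(f$coefficients), c(2, 3), tolerance = 1e-12)
  expect_false(f$rank_deficient)
  # closed-form simple-regression slope
  set.seed(5)
  y <- rnorm(12)
  f2 <- fit_linear_model(X, y)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(f2$coefficients[["x"]], slope, tolerance = 1e-12)
  # t = coefficient / std_error wherever defined
  expect_equal(f2$t_values, f2$coefficients / f2$std_errors, tolerance = 1e-12)
  # duplicated column
  f3 <- fit_linear_model(cbind(X, x2 = x), y)
  expect_true(f3$rank_deficient)
  expect_true(any(is.na(f3$coefficients)))
  # zero residual df: coefficients returned, inference unavailable
  f4 <- fit_linear_model(X[1:2, ], y[1:2])
  expect_equal(f4$df_residual, 0)
  expect_true(all(is.na(f4$p_values)))
})

test_that("least squares inference matches R's lm summary", {
  set.seed(6)
  x1 <- rnorm(40); x2 <- rnorm(40)
  y <- 1 + 2 * x1 - x2 + rnorm(40)
  X <- cbind(`(Intercept)` = 1, x1 = x1, x2 = x2)
  f <- fit_linear_model(X, y)
  s <- summary(lm(y ~ x1 + x2))$coefficients
  expect_equal(unname(f$coefficients), unname(s[, 1]), tolerance = 1e-10)
  expect_equal(unname(f$std_errors), unname(s[, 2]), tolerance = 1e-10)
  expect_equal(unname(f$p_values), unname(s[, 4]), tolerance = 1e-10)
})

test_that("OLS confidence intervals cover planted coefficients at the nominal rate", {
  covered <- 0L
  for (s in 1:100) {
    set.seed(s)
    x <- rnorm(200)
    y <- 2 + 3 * x + rnorm(200)
    f <- fit_linear_model(cbind(i = 1, x = x), y)
    lo <- f$coefficients - stats::qt(0.975, f$df_residual) * f$std_errors
    hi <- f$coefficients + stats::qt(0.975, f$df_residual) * f$std_errors
    if (all(lo <= c(2, 3) & c(2, 3) <= hi)) covered <- covered + 1L
  }
  expect_gte(covered, 90)
})
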