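test_that("ICC is 1 when repeats are identical and subjects differ", {
  m <- cbind(c(1, 2, 5, 9), c(1, 2, 5, 9))
  r <- icc_oneway(m)
  expect_identical(r$estimate, 1)
  expect_identical(c(r$ci_low, r$ci_high), c(1, 1))
  expect_identical(r$category, "excellent")
})

test_that("ICC matches an explicit sums-of-squares oracle", {
  m <- cbind(c(1, 2, 5, 9), c(2, 3, 6, 8))
  expect_equal(icc_oneway(m)$estimate, oracle_icc_oneway(m),
               tolerance = 1e-12)
  withr::with_seed(7, {
    for (i in 1:25) {
      n <- sample(3:50, 1)
      mm <- matrix(rnorm(2 * n, 15, 4), n, 2)
      mm[, 2] <- mm[, 1] + rnorm(n, 0, 1.5)
      r <- icc_oneway(mm)
      expect_equal(r$estimate, oracle_icc_oneway(mm), tolerance = 1e-12)
      expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)
    }
  })
})

test_that("ICC is invariant under positive affine transformation", {
  withr::with_seed(3, m <- matrix(rnorm(40, 20, 5), 20, 2))
  expect_equal(icc_oneway(2.7 * m + 13)$estimate, icc_oneway(m)$estimate,
               tolerance = 1e-12)
})

test_that("ICC accepts balanced long tables and rejects unbalanced ones", {
  df <- data.frame(
    subject_id = rep(c("a", "b", "c"), each = 2),
    value = c(1, 1.1, 4, 4.2, 9, 8.8)
  )
  m <- matrix(df$value, ncol = 2, byrow = TRUE)
  expect_equal(icc_oneway(df)$estimate, icc_oneway(m)$estimate)
  bad <- df[-1, ]
  expect_error(icc_oneway(bad), "unbalanced")
})

test_that("ICC interpretation bands follow the documented boundaries", {
  expect_identical(interpret_icc(0.3), "poor")
  expect_identical(interpret_icc(0.5), "moderate")
  expect_identical(interpret_icc(0.641), "moderate")
  expect_identical(interpret_icc(0.75), "good")
  expect_identical(interpret_icc(0.883), "good")
  expect_identical(interpret_icc(0.9), "good")
  expect_identical(interpret_icc(0.901), "excellent")
  expect_identical(interpret_icc(0.971), "excellent")
})

test_that("Bland-Altman reproduces trivial and constant-offset cases", {
  x <- c(10, 12, 15, 18)
  r0 <- bland_altman(x, x)
  expect_equal(r0$bias, 0)
  expect_equal(c(r0$loa_lower, r0$loa_upper), c(0, 0))

  r2 <- bland_altman(x + 2, x)
  expect_equal(r2$bias, 2)
  expect_equal(r2$sd_diff, 0)
  expect_equal(c(r2$loa_lower, r2$loa_upper), c(2, 2))
  expect_equal(r2$mean_of_means, mean(x) + 1)
})

test_that("Bland-Altman is antisymmetric in the pair order", {
  withr::with_seed(11, {
    a <- rnorm(30, 16, 4)
    b <- a + rnorm(30, 0.5, 1)
  })
  f <- bland_altman(a, b)
  g <- bland_altman(b, a)
  expect_equal(g$bias, -f$bias)
  expect_equal(g$loa_lower, -f$loa_upper)
  expect_equal(g$loa_upper, -f$loa_lower)
  expect_equal(g$mean_of_means, f$mean_of_means)
})

test_that("within-subject SD matches hand arithmetic and sqrt(MSW)", {
  expect_equal(within_subject_sd(matrix(c(0, 2), 1, 2,
                                        dimnames = NULL)), sqrt(2))
  m <- cbind(c(1, 1, 1), c(1, 1, 1))
  expect_equal(within_subject_sd(m), 0)
  withr::with_seed(13, mm <- matrix(rnorm(60, 20, 3), 30, 2))
  expect_equal(within_subject_sd(mm), sqrt(icc_oneway(mm)$msw),
               tolerance = 1e-12)
})

test_that("Levene F is zero for identical dispersion profiles", {
  small <- cbind(c(10, 12, 14, 16), c(11, 15, 16, 20))  # |d| = 1, 3, 2, 4
  large <- cbind(c(20, 22, 24, 26), c(21, 25, 26, 30))  # same dispersions
  r <- levene_size_comparison(small, large)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$df, c(1, 6))
})

test_that("Levene equals the two-sample pooled-variance F on the scores", {
  withr::with_seed(21, {
    ms <- matrix(rnorm(60, 15, 3), 30, 2)
    ml <- matrix(rnorm(60, 15, 1.5), 30, 2)
  })
  r <- levene_size_comparison(ms, ml)
  ss <- abs(ms[, 1] - ms[, 2]) / sqrt(2)
  sl <- abs(ml[, 1] - ml[, 2]) / sqrt(2)
  tt <- t.test(ss, sl, var.equal = TRUE)
  expect_equal(r$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("Spearman handles monotone, antitone and tied data", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_bootstrap(x, x, n_boot = 50)$rho, 1)
  expect_equal(spearman_bootstrap(x, -x, n_boot = 50)$rho, -1)
  withr::with_seed(31, {
    a <- round(runif(50, 0, 10))  # plenty of ties
    b <- a + rnorm(50, 0, 2)
  })
  r <- spearman_bootstrap(a, b, n_boot = 100, seed = 5)
  expect_equal(r$rho, oracle_spearman(a, b), tolerance = 1e-12)
  r2 <- spearman_bootstrap(a, b, n_boot = 100, seed = 5)
  expect_identical(c(r$ci_low, r$ci_high), c(r2$ci_low, r2$ci_high))
  expect_true(r$ci_low <= r$rho && r$rho <= r$ci_high)
  expect_warning(out <- spearman_bootstrap(rep(1, 6), x, n_boot = 10),
                 "constant")
  expect_true(is.na(out$rho))
})

test_that("reliability sample size reproduces the reference configuration", {
  expect_identical(walter_sample_size(0.75, 0.9, k = 2, alpha = 0.05,
                                      power = 0.8), 33L)
})

test_that("sample size is monotone in effect size, power and k", {
  base <- walter_sample_size(0.75, 0.9, k = 2)
  expect_lt(walter_sample_size(0.5, 0.9, k = 2), base)
  expect_lt(walter_sample_size(0.75, 0.9, k = 2, power = 0.6), base)
  expect_lte(walter_sample_size(0.75, 0.9, k = 3), base)
  expect_lt(walter_sample_size(0.75, 0.9, k = 2, two_sided = FALSE), base)
  expect_error(walter_sample_size(0.9, 0.75), "exceed")
})

test_that("degenerate agreement inputs are rejected", {
  expect_error(icc_oneway(matrix(1, 1, 2)))
  expect_error(bland_altman(1, numeric(0)))
  expect_error(levene_size_comparison(matrix(1:2, 1, 2), matrix(1:4, 2, 2)))
  expect_error(spearman_bootstrap(1:3, 1:3))
})
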