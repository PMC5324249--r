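test_that("least squares reproduces exact lines and the normal equations", {
  a <- seq(10, 40, length.out = 20)
  same <- least_squares(paired_measures(a, a))
  expect_equal(same$slope, 1)
  expect_equal(same$intercept, 0)
  expect_equal(same$r_value, 1)

  aff <- least_squares(paired_measures(a, 2 * a + 1))
  expect_equal(aff$slope, 2)
  expect_equal(aff$intercept, 1)
  expect_equal(aff$r_value, 1)

  set.seed(21)
  x <- stats::runif(100, 10, 40)
  y <- 0.9 * x + stats::rnorm(100, 0, 1)
  fit <- least_squares(paired_measures(x, y))
  # closed-form normal equations
  sl <- (mean(x * y) - mean(x) * mean(y)) / (mean(x^2) - mean(x)^2)
  ic <- mean(y) - sl * mean(x)
  expect_equal(fit$slope, sl, tolerance = 1e-10)
  expect_equal(fit$intercept, ic, tolerance = 1e-10)
  expect_equal(fit$r_value^2, cor(x, y)^2, tolerance = 1e-12)
  expect_lt(fit$p_value, 1e-10)
  expect_error(least_squares(paired_measures(rep(2, 5), 1:5)), "constant")
})

test_that("Bland-Altman bias, limits and coefficient follow the 1.96 SD rule", {
  a <- c(10, 12, 14, 16)
  ba <- bland_altman(paired_measures(a, a + 2))
  expect_equal(ba$bias, -2)
  expect_equal(ba$reproducibility_coefficient, 0)
  expect_equal(ba$loa_low, -2)
  expect_equal(ba$loa_high, -2)

  # d in {-1, 0, +1}: bias 0, SD 1, limits +/- 1.96
  ba2 <- bland_altman(paired_measures(c(1, 2, 3), c(2, 2, 2)))
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$sd_diff, 1)
  expect_equal(ba2$loa_low, -1.96)
  expect_equal(ba2$loa_high, 1.96)
  expect_equal(ba2$reproducibility_coefficient, 1.96)

  # limits symmetric about the bias; invariant to a common shift
  set.seed(2)
  x <- stats::rnorm(50, 25, 4)
  y <- x + stats::rnorm(50, -0.5, 1.5)
  b1 <- bland_altman(paired_measures(x, y))
  expect_equal(b1$loa_high - b1$bias, b1$bias - b1$loa_low,
               tolerance = 1e-12)
  b2 <- bland_altman(paired_measures(x + 100, y + 100))
  expect_equal(b2$bias, b1$bias, tolerance = 1e-12)
  expect_equal(b2$reproducibility_coefficient,
               b1$reproducibility_coefficient, tolerance = 1e-12)
})

test_that("Bland-Altman bias estimate lands in its sampling band", {
  set.seed(31)
  d <- stats::rnorm(200, -0.8, 2.2)
  a <- stats::runif(200, 15, 35)
  ba <- bland_altman(paired_measures(a, a - d))
  # SE of the mean = 2.2 / sqrt(200) ~ 0.156; +/- 0.35 is a ~2.2 sigma band
  expect_lt(abs(ba$bias - (-0.8)), 0.35)
})

test_that("Passing-Bablok recovers exact lines and the shifted-median oracle", {
  a <- seq(15, 35, length.out = 30)
  pb0 <- passing_bablok(paired_measures(a, a))
  expect_equal(pb0$slope, 1)
  expect_equal(pb0$intercept, 0)

  pb <- passing_bablok(paired_measures(a, 0.85 * a + 4.01))
  expect_equal(pb$slope, 0.85, tolerance = 1e-12)
  expect_equal(pb$intercept, 4.01, tolerance = 1e-12)
  expect_true(pb$slope_lower <= pb$slope && pb$slope <= pb$slope_upper)
  expect_true(pb$intercept_lower <= pb$intercept &&
                pb$intercept <= pb$intercept_upper)

  set.seed(13)
  for (rep in 1:3) {
    x <- stats::runif(15, 10, 40)
    y <- 0.9 * x + stats::rnorm(15, 0, 2)
    est <- passing_bablok(paired_measures(x, y))$slope
    ij <- utils::combn(15, 2)
    S <- (y[ij[2, ]] - y[ij[1, ]]) / (x[ij[2, ]] - x[ij[1, ]])
    S <- sort(S[is.finite(S) & S != -1])
    K <- sum(S < -1)
    N <- length(S)
    oracle <- if (N %% 2 == 1) S[(N + 1) / 2 + K] else
      mean(S[N / 2 + K + 0:1])
    expect_equal(est, oracle, tolerance = 1e-12)
  }
  expect_error(passing_bablok(paired_measures(rep(3, 10), 1:10)),
               "constant")
})

test_that("Passing-Bablok is scale-equivariant and swap-reciprocal", {
  set.seed(17)
  x <- stats::runif(25, 10, 40)
  y <- 0.8 * x + 3 + stats::rnorm(25, 0, 1)
  pb <- passing_bablok(paired_measures(x, y))
  pb_scaled <- passing_bablok(paired_measures(3 * x, 3 * y))
  expect_equal(pb_scaled$slope, pb$slope, tolerance = 1e-12)
  expect_equal(pb_scaled$intercept, 3 * pb$intercept, tolerance = 1e-12)
  pb_swap <- passing_bablok(paired_measures(y, x))
  expect_equal(pb_swap$slope, 1 / pb$slope, tolerance = 1e-6)
})

test_that("variance-ratio concordance compares against the F critical value", {
  z <- c(1, 2, 3, 4, 5)
  same <- f_concordance(z, z + 10)
  expect_equal(same$f_value, 1)
  expect_true(same$concordant)

  set.seed(6)
  a <- stats::rnorm(21, 0, 2)  # variance 4
  b <- stats::rnorm(21, 0, 1)
  a <- a / sd(a) * 2           # force the sample variances exactly
  b <- b / sd(b)
  fc <- f_concordance(a, b)
  expect_equal(fc$f_value, 4, tolerance = 1e-12)
  # larger variance in the numerator, so the size-0.05 critical value is
  # the upper 2.5% point (2.46 for 20, 20 df); F = 4 is discordant either way
  expect_equal(fc$f_crit, qf(0.975, 20, 20), tolerance = 1e-12)
  expect_equal(fc$f_crit, 2.46, tolerance = 0.005)
  expect_false(fc$concordant)

  both_const <- f_concordance(rep(1, 5), rep(2, 7))
  expect_equal(both_const$f_value, 1)
  expect_true(both_const$concordant)
  expect_error(f_concordance(1, 1:5), "at least 2")
})

test_that("the F test holds its nominal type-I error on null replicates", {
  set.seed(123)
  rejections <- vapply(seq_len(500), function(i) {
    !f_concordance(stats::rnorm(30), stats::rnorm(30))$concordant
  }, logical(1))
  rate <- mean(rejections)
  expect_gte(rate, 0.025)
  expect_lte(rate, 0.08)
})

test_that("the agreement report bundles and tidies all statistics", {
  set.seed(40)
  a <- stats::runif(40, 15, 40)
  b <- 0.95 * a + 1 + stats::rnorm(40, 0, 1.2)
  rep <- agreement_report(paired_measures(a, b))
  td <- tidy(rep)
  expect_setequal(td$term, c("ls_slope", "ls_intercept", "r_value", "bias",
                             "reproducibility_coefficient", "pb_slope",
                             "pb_intercept"))
  expect_equal(td$estimate[td$term == "bias"], rep$bland_altman$bias)
  gl <- glance(rep)
  expect_equal(gl$n, 40)
  expect_equal(gl$r_value, rep$least_squares$r_value)
  # loa span = 2 x reproducibility coefficient
  expect_equal(gl$loa_high - gl$loa_low,
               2 * rep$bland_altman$reproducibility_coefficient,
               tolerance = 1e-12)
  expect_output(print(rep), "Passing-Bablok")
})

test_that("paired measures validate their inputs", {
  expect_error(paired_measures(1:3, 1:4), "equal length")
  expect_error(paired_measures(1:2, 1:2), "at least 3")
  expect_error(paired_measures(c(1, NA, 3), 1:3), "finite")
})
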