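# Fixtures are checked against independent oracles: base R's stats
# implementations (lm/confint, t.test, cor.test, kruskal.test) and direct
# normal-equation / ANOVA computations.

test_that("fit_ols matches exact fits and the lm/confint oracle", {
  x <- 1:5
  expect_fit <- fit_ols(x, 2 * x + 1)
  expect_equal(expect_fit$slope, 2, tolerance = 1e-12)
  expect_equal(expect_fit$intercept, 1, tolerance = 1e-12)
  expect_equal(expect_fit$r_squared, 1, tolerance = 1e-12)

  set.seed(21)
  for (i in 1:3) {
    x <- rnorm(10, 50, 10)
    y <- 0.7 * x + rnorm(10, 5, 4)
    f <- fit_ols(x, y)
    m <- lm(y ~ x)
    ci <- confint(m)
    expect_equal(f$slope, unname(coef(m)[2]), tolerance = 1e-9)
    expect_equal(f$intercept, unname(coef(m)[1]), tolerance = 1e-9)
    expect_equal(f$slope_ci, unname(ci[2, ]), tolerance = 1e-9)
    expect_equal(f$intercept_ci, unname(ci[1, ]), tolerance = 1e-9)
    expect_equal(f$p_value, summary(m)$coefficients[2, 4], tolerance = 1e-9)
    # R^2 = PCC^2 invariant
    expect_equal(f$r_squared, f$pcc^2, tolerance = 1e-9)
    expect_equal(f$pcc, pearson_cor(x, y)$r, tolerance = 1e-12)
  }
  expect_error(fit_ols(rep(1, 5), 1:5), "degenerate-regressor")
})

test_that("fit_ols null simulation: independent data give near-zero slope", {
  set.seed(5)
  x <- rnorm(1e4); y <- rnorm(1e4)
  expect_lt(abs(fit_ols(x, y)$slope), 0.05)
})

test_that("pearson_cor matches cor.test and handles perfect correlation", {
  expect_equal(pearson_cor(1:10, 1:10)$r, 1)
  expect_equal(pearson_cor(1:10, -(1:10))$r, -1)
  set.seed(31)
  x <- rnorm(10); y <- rnorm(10, x)
  ct <- cor.test(x, y)
  pc <- pearson_cor(x, y)
  expect_equal(pc$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pc$p, ct$p.value, tolerance = 1e-9)
  expect_error(pearson_cor(rep(2, 5), 1:5), "degenerate")
})

test_that("paired_t matches t.test and degenerate rules", {
  a <- c(44, 52, 39, 61, 47, 50, 42, 58)
  b <- c(40, 49, 41, 55, 45, 52, 39, 50)
  pt_ <- paired_t(a, b)
  or <- t.test(a, b, paired = TRUE)
  expect_equal(pt_$t, unname(or$statistic), tolerance = 1e-9)
  expect_equal(pt_$p, or$p.value, tolerance = 1e-9)
  expect_equal(pt_$mean_difference, unname(or$estimate), tolerance = 1e-12)
  # exact agreement
  same <- paired_t(a, a)
  expect_equal(same$mean_difference, 0)
  expect_equal(same$p, 1)
  expect_error(paired_t(a, a + 5), "degenerate")
  # power: a clear shift is detected
  set.seed(9)
  z <- rnorm(50, 45, 8)
  expect_lt(paired_t(z + 5 + rnorm(50, 0, 1), z)$p, 0.05)
})

test_that("bland_altman matches the direct formula and shift equivariance", {
  set.seed(2)
  a <- rnorm(10, 50, 8); b <- a + rnorm(10, 2, 3)
  ba <- bland_altman(a, b)
  d <- a - b
  expect_equal(ba$mean_difference, mean(d), tolerance = 1e-12)
  expect_equal(ba$loa_lower, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba$loa_upper, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  same <- bland_altman(a, a)
  expect_equal(same$mean_difference, 0)
  expect_equal(same$loa_lower, 0)
  # shifting the comparison shifts the mean difference, not the SD
  sh <- bland_altman(a, b + 7)
  expect_equal(sh$mean_difference, ba$mean_difference - 7, tolerance = 1e-12)
  expect_equal(sh$sd_difference, ba$sd_difference, tolerance = 1e-12)
  # limits contain ~95% of differences on normal data
  set.seed(3)
  a <- rnorm(1000); b <- a + rnorm(1000)
  ba <- bland_altman(a, b)
  inside <- mean((a - b) >= ba$loa_lower & (a - b) <= ba$loa_upper)
  expect_gte(inside, 0.90)
})

test_that("icc matches a brute-force two-way ANOVA oracle", {
  expect_equal(icc(c(1, 2, 3, 5), c(1, 2, 3, 5))$icc, 1, tolerance = 1e-12)
  a <- c(51, 48, 60, 44, 56, 39)
  b <- c(49, 50, 57, 46, 58, 37)
  # oracle: mean squares from aov, ICC(A,1) formula assembled independently
  df <- data.frame(y = c(a, b),
                   subj = factor(rep(1:6, 2)),
                   rater = factor(rep(1:2, each = 6)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 6; k <- 2
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  expect_equal(icc(a, b)$icc, oracle, tolerance = 1e-9)
  # null: shuffled ratings decorrelate
  set.seed(4)
  x <- rnorm(100, 50, 10)
  expect_lt(abs(icc(x, sample(x))$icc), 0.2)
  # invariance under a common shift of both raters
  expect_equal(icc(a + 10, b + 10)$icc, icc(a, b)$icc, tolerance = 1e-12)
  expect_error(icc(rep(5, 4), rep(5, 4)), "undefined-ICC")
})

test_that("kruskal_wallis matches kruskal.test including tie correction", {
  g1 <- c(40, 42, 42, 45); g2 <- c(41, 42, 47, 48); g3 <- c(39, 44, 44, 50)
  kw <- kruskal_wallis(list(g1, g2, g3))
  or <- kruskal.test(list(g1, g2, g3))
  expect_equal(kw$H, unname(or$statistic), tolerance = 1e-9)
  expect_equal(kw$p, or$p.value, tolerance = 1e-9)
  same <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$H, 0, tolerance = 1e-12)
  expect_gt(same$p, 0.99)
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "degenerate")
  # power: 10 HU shift with n = 30 per group
  set.seed(6)
  base <- rnorm(30, 40, 8)
  expect_lt(kruskal_wallis(list(base, rnorm(30, 50, 8)))$p, 0.05)
})
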