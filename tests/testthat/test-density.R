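test_that("sample_density is a direct voxel lookup", {
  v <- volume3d(array(0, c(3, 1, 1)), spacing = c(1, 1, 1))
  v$voxels[] <- c(40, 50, 60)
  m <- voxel_mask(array(TRUE, c(3, 1, 1)), thrombodens:::as_grid(v))
  s <- sample_density(v, m)
  expect_equal(sort(s$values), c(40, 50, 60))
  expect_equal(length(s$values), mask_count(m))
  # full-volume mask: sample size equals voxel count
  v2 <- volume3d(array(rnorm(4 * 4 * 4), c(4, 4, 4)))
  mfull <- voxel_mask(array(TRUE, c(4, 4, 4)), thrombodens:::as_grid(v2))
  expect_equal(length(sample_density(v2, mfull)$values), 64L)
  m0 <- voxel_mask(array(FALSE, c(4, 4, 4)), thrombodens:::as_grid(v2))
  expect_error(sample_density(v2, m0), "empty-mask")
})

test_that("summarize_density: constant and uniform-ladder closed forms", {
  s <- summarize_density(density_sample(c(50, 50, 50, 50), 1))
  expect_equal(s$median, 50)
  expect_equal(s$iqr, 0)
  expect_equal(s$sd, 0)
  expect_equal(s$skewness, 0)
  expect_equal(s$kurtosis, 0)
  expect_true(s$degenerate)
  expect_true(is.na(s$is_normal))

  u <- summarize_density(density_sample(1:100, 2))
  expect_equal(u$median, 50.5)
  expect_equal(u$iqr, 49.5)   # type-7 quantiles: Q1 = 25.75, Q3 = 75.25
  expect_equal(u$q1, 25.75)
  expect_equal(u$q3, 75.25)
  expect_equal(u$skewness, 0, tolerance = 1e-12)
  expect_equal(u$volume_mm3, 200)
})

test_that("skewness/kurtosis match the bias-corrected oracle formulas", {
  set.seed(8)
  x <- rgamma(200, shape = 2) * 10
  n <- length(x)
  # independent oracle: moment route, G1 = g1*sqrt(n(n-1))/(n-2),
  # G2 = ((n+1)*g2 + 6) * (n-1)/((n-2)(n-3))
  m2 <- mean((x - mean(x))^2); m3 <- mean((x - mean(x))^3)
  m4 <- mean((x - mean(x))^4)
  g1 <- m3 / m2^1.5; g2 <- m4 / m2^2 - 3
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  G2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  s <- summarize_density(density_sample(x, 1))
  expect_equal(s$skewness, G1, tolerance = 1e-9)
  expect_equal(s$kurtosis, G2, tolerance = 1e-9)
})

test_that("median/IQR permutation invariance and shift equivariance", {
  set.seed(10)
  x <- rnorm(500, 45, 12)
  s1 <- summarize_density(density_sample(x, 1))
  s2 <- summarize_density(density_sample(sample(x), 1))
  expect_equal(s1$median, s2$median)
  expect_equal(s1$iqr, s2$iqr)
  sh <- summarize_density(density_sample(x + 13.5, 1))
  for (f in c("mean", "median", "min", "max"))
    expect_equal(sh[[f]], s1[[f]] + 13.5, tolerance = 1e-9)
  for (f in c("sd", "iqr", "skewness", "kurtosis"))
    expect_equal(sh[[f]], s1[[f]], tolerance = 1e-9)
})

test_that("exactly symmetric samples have zero skewness", {
  x <- c(30, 35, 40, 45, 50, 55, 60)
  expect_lt(abs(summarize_density(density_sample(x, 1))$skewness), 1e-12)
  y <- c(x, rev(100 - x))  # symmetric by construction
  y <- y - mean(y)
  expect_lt(abs(summarize_density(density_sample(y, 1))$skewness), 1e-12)
})

test_that("large normal samples: near-zero shape, calibrated Shapiro-Wilk", {
  set.seed(12)
  x <- rnorm(1e5)
  s <- summarize_density(density_sample(x, 1))
  expect_lt(abs(s$skewness), 0.05)
  expect_lt(abs(s$kurtosis), 0.1)
  expect_equal(s$n_voxels, 1e5)
  # Shapiro on capped subsample runs without error on huge samples
  expect_true(is.finite(s$normality_p))
  # rejection rate ~ alpha across 100 normal samples
  rej <- sum(vapply(1:100, function(i) {
    summarize_density(density_sample(rnorm(300, 45, 10), 1))$normality_p <= 0.05
  }, logical(1)))
  expect_lte(rej, 12)
})
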