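test_that("phantom_spec validates its invariants", {
  expect_error(phantom_spec(spacing = c(0.5, 0.5, 3)), "slice")
  expect_error(phantom_spec(thrombus_arc = c(0.6, 0.4)), "arc")
  expect_error(phantom_spec(noise_sd = -1), "noise")
  expect_error(phantom_spec(
    thrombus_mix = data.frame(weight = c(0.5, 0.6), mean = c(30, 60), sd = 2)),
    "weights")
})

test_that("identical seeds give bit-identical phantoms", {
  sp <- small_phantom_spec(seed = 11)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$cta$voxels, b$cta$voxels)
  expect_identical(a$ncct$voxels, b$ncct$voxels)
  expect_identical(a$truth$misalignment$rotation, b$truth$misalignment$rotation)
  c <- generate_phantom(small_phantom_spec(seed = 12))
  expect_false(identical(a$ncct$voxels, c$ncct$voxels))
})

test_that("noiseless unblurred single-component thrombus is exactly constant", {
  sp <- small_phantom_spec(
    noise_sd = 0, blur_fwhm = 0,
    thrombus_mix = data.frame(weight = 1, mean = 50, sd = 0))
  ph <- generate_phantom(sp)
  vals <- sample_density(ph$ncct, ph$truth$thrombus_ncct)$values
  expect_true(all(vals == 50))
  # and the truth summary equals the measured summary exactly
  m <- summarize_density(sample_density(ph$ncct, ph$truth$thrombus_ncct))
  expect_equal(m$median, ph$truth$density_summary$median)
  expect_equal(m$iqr, ph$truth$density_summary$iqr)
})

test_that("noiseless thrombus voxels follow the specified mixture", {
  # Monte-Carlo quantile oracle on 1e6 iid mixture draws. For the
  # equal-weight two-component mixture the CDF is flat at 0.5 between the
  # modes, so the *median* of any finite draw is unstable across the gap;
  # the mean and the outer quartiles are the stable functionals and are the
  # ones compared here.
  mix <- data.frame(weight = c(0.5, 0.5), mean = c(30, 60), sd = 2)
  oracle <- thrombodens:::with_seed(99, {
    comp <- sample(1:2, 1e6, replace = TRUE, prob = mix$weight)
    draws <- rnorm(1e6, mix$mean[comp], mix$sd[comp])
    c(mean = mean(draws), quantile(draws, c(0.25, 0.75), names = FALSE))
  })
  sp <- small_phantom_spec(noise_sd = 0, blur_fwhm = 0, thrombus_mix = mix,
                           seed = 21)
  ph <- generate_phantom(sp)
  vals <- ph$truth$thrombus_hu
  expect_gt(length(vals), 300)
  expect_lt(abs(mean(vals) - oracle[1]), 3)
  expect_lt(abs(quantile(vals, 0.25, names = FALSE) - oracle[2]), 3)
  expect_lt(abs(quantile(vals, 0.75, names = FALSE) - oracle[3]), 3)
  # for the unequal-weight default mixtures the median is pinned to the
  # middle component and is stable
  mix3 <- data.frame(weight = c(0.3, 0.4, 0.3), mean = c(25, 45, 65), sd = 2)
  ph3 <- generate_phantom(small_phantom_spec(noise_sd = 0, blur_fwhm = 0,
                                             thrombus_mix = mix3, seed = 22))
  expect_lt(abs(ph3$truth$density_summary$median - 45), 3)
})

test_that("CTA lumen enhances and the tree is mirror-symmetric", {
  sp <- small_phantom_spec(seed = 31)
  ph <- generate_phantom(sp)
  # lumen voxels away from the wall average to background + enhancement
  core <- erode_mask(ph$truth$contralateral, 1.0)
  expect_gt(mask_count(core), 50)
  expect_lt(abs(mean(ph$cta$voxels[core$mask]) -
                (sp$background_hu + sp$cta_enhancement)), 10)
  # reflecting the contralateral tree about the true plane covers the
  # occluded-side tree (before misalignment; both live on the CTA grid)
  refl <- mirror_mask(ph$truth$contralateral, ph$truth$plane)
  expect_gte(dice(refl, ph$truth$occluded_tree), 0.95)
  # the two thrombus masks correspond under the true misalignment
  proj <- apply_transform(ph$truth$thrombus_cta, ph$truth$misalignment,
                          thrombodens:::as_grid(ph$ncct))
  expect_gte(dice(proj, ph$truth$thrombus_ncct), 0.8)
  expect_equal(sqrt(sum(ph$truth$plane$normal^2)), 1, tolerance = 1e-9)
})

test_that("noise SD increases measured thrombus spread monotonically", {
  sds <- c(0, 5, 10)
  spread <- vapply(sds, function(ns) {
    mean(vapply(1:20, function(s) {
      ph <- generate_phantom(small_phantom_spec(
        seed = 100 + s, noise_sd = ns,
        thrombus_mix = data.frame(weight = 1, mean = 45, sd = 2)))
      sd(sample_density(ph$ncct, ph$truth$thrombus_ncct)$values)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(spread) > 0))
})

test_that("sample_cohort_specs hits the target ranges deterministically", {
  specs <- sample_cohort_specs(100, seed = 5)
  med <- vapply(specs, function(s) attr(s, "target_median"), numeric(1))
  iqr <- vapply(specs, function(s) attr(s, "target_iqr"), numeric(1))
  expect_true(all(med >= 20 & med <= 64))
  expect_true(all(iqr >= 9 & iqr <= 56))
  specs2 <- sample_cohort_specs(100, seed = 5)
  expect_identical(lapply(specs, unclass), lapply(specs2, unclass))
  expect_length(sample_cohort_specs(1, seed = 1), 1L)
  # realised truth tracks the targets
  ph <- generate_phantom(specs[[1]])
  expect_lt(abs(ph$truth$density_summary$median - med[1]), 5)
})
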