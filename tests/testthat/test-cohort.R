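rec_with <- function(id, st = 1, gap = 5, med = 45) {
  ds <- summarize_density(density_sample(rnorm(50, med, 5), 1))
  cohort_record(id, slice_thickness_mm = st, time_gap_min = gap,
                density_summary = ds,
                manual = list(obs1 = med + 5, obs2 = med + 4))
}

test_that("filter_cohort applies the exclusion rules with strict boundaries", {
  recs <- list(
    rec_with("a", st = 3.0, gap = 5),     # slice thickness > 2.5: out
    rec_with("b", st = 2.5, gap = 10),    # boundary: in
    rec_with("c", st = 1.0, gap = 45),    # time gap > 30: out
    rec_with("d", st = 1.0, gap = 30),    # boundary: in
    rec_with("e", st = NA, gap = 5))      # missing metadata: flagged out
  fc <- filter_cohort(recs)
  expect_equal(vapply(fc$included, function(r) r$case_id, ""), c("b", "d"))
  reasons <- lapply(fc$excluded, function(r) r$exclusion_reasons)
  expect_equal(reasons[[1]], "slice_thickness")
  expect_equal(reasons[[2]], "time_gap")
  expect_equal(reasons[[3]], "missing_slice_thickness")
  # exhaustive and disjoint; re-filtering partitions identically
  expect_equal(length(fc$included) + length(fc$excluded), length(recs))
  fc2 <- filter_cohort(c(fc$included, fc$excluded))
  expect_equal(length(fc2$included), length(fc$included))
})

test_that("summarize_cohort reproduces hand-computed aggregates", {
  r1 <- rec_with("a"); r2 <- rec_with("b")
  r1$density_summary$median <- 40; r2$density_summary$median <- 50
  tab1 <- summarize_cohort(list(r1))
  row <- tab1[tab1$statistic == "Median", ]
  expect_equal(row$average, 40)
  expect_equal(row$sd, 0)
  tab <- summarize_cohort(list(r1, r2))
  row <- tab[tab$statistic == "Median", ]
  expect_equal(row$average, 45)
  expect_equal(row$min, 40)
  expect_equal(row$max, 50)
  # permutation invariance
  tab_rev <- summarize_cohort(list(r2, r1))
  expect_equal(tab$average, tab_rev$average)
  # manual observers aggregated per observer and pooled
  expect_true(all(c("obs1", "obs2", "All Observers") %in% tab$statistic))
})

make_synthetic_s1 <- function(n = 135, seed = 19) {
  # synthetic stand-in for a per-thrombus cohort table with a known
  # manual/median relationship (see replication tests)
  thrombodens:::with_seed(seed, {
    median <- runif(n, 20, 64)
    iqr <- runif(n, 9, 56)
    data.frame(
      case = seq_len(n), median = median, mean = median + rnorm(n, 0, 2),
      sd = iqr / 1.35 + rnorm(n, 0, 1), iqr = iqr,
      skewness = rnorm(n, 0, 0.4), kurtosis = rnorm(n, -0.3, 0.7),
      volume_mm3 = pmax(5, rnorm(n, 52, 38)),
      obs1 = 0.5 * median + 25 + rnorm(n, 0, 4),
      obs2 = c(0.5 * median[1:77] + 26 + rnorm(77, 0, 4), rep(NA, n - 77)),
      obs3 = c(rep(NA, n - 61), 0.5 * median[(n - 60):n] + 22 + rnorm(61, 0, 4)))
  })
}

test_that("replicate_analysis recovers a constructed manual/median slope", {
  s1 <- make_synthetic_s1()
  res <- replicate_analysis(s1)
  f <- res$regression$manual_on_median
  expect_gt(f$slope_ci[1], 0.40)
  expect_lt(f$slope_ci[2], 0.60)   # true slope 0.5 inside the CI
  expect_true(f$slope_ci[1] <= 0.5 && 0.5 <= f$slope_ci[2])
  # paired t: manual constructed above median on average
  expect_gt(res$delta$median$mean_difference, 0)
  expect_lt(res$delta$median$p, 0.05)
  # interobserver blocks use complete-case pairing
  expect_equal(res$interobserver$obs1_obs2$n, 77)
  expect_equal(res$interobserver$obs1_obs3$n, 61)
  expect_lte(res$interobserver$obs1_obs2$icc$icc, 1)
  # deterministic: identical input, identical output
  expect_identical(res$descriptives, replicate_analysis(s1)$descriptives)
  expect_error(replicate_analysis(s1[, setdiff(names(s1), "median")]),
               "schema error.*median")
})

test_that("run_case errors at segment_thrombus when the artery is patent", {
  # a "no occlusion" scene: the would-be thrombus enhances like lumen
  sp <- small_phantom_spec(
    seed = 91,
    thrombus_mix = data.frame(weight = 1, mean = 200, sd = 2))
  ph <- generate_phantom(sp)
  expect_error(run_case(ph$cta, ph$ncct, ph$truth$seeds),
               "segment_thrombus.*no-thrombus-found")
})

test_that("run_case recovers the phantom median end to end", {
  ph <- generate_phantom(phantom_spec(seed = 8))
  rec <- run_case(ph$cta, ph$ncct, ph$truth$seeds,
                  config = list(case_id = "p8"))
  expect_s3_class(rec$density_summary, "density_summary")
  expect_lt(abs(rec$density_summary$median - ph$truth$density_summary$median), 3)
  expect_lt(abs(rec$density_summary$volume_mm3 -
                ph$truth$density_summary$volume_mm3) /
              ph$truth$density_summary$volume_mm3, 0.25)
  expect_true(all(c("segment_contralateral", "register_rigid", "summarize")
                  %in% rec$artifacts$log$stage))
})

test_that("run_cohort consumes a file manifest", {
  dir <- file.path(tempdir(), "cohort")
  dir.create(dir, showWarnings = FALSE)
  ph <- generate_phantom(small_phantom_spec(seed = 92))
  write_volume(ph$cta, file.path(dir, "cta.nii.gz"))
  write_volume(ph$ncct, file.path(dir, "ncct.nii.gz"))
  manifest <- data.frame(
    case_id = "m1", cta = file.path(dir, "cta.nii.gz"),
    ncct = file.path(dir, "ncct.nii.gz"),
    seed1 = paste(ph$truth$seeds[1, ], collapse = ","),
    seed2 = paste(ph$truth$seeds[2, ], collapse = ","),
    time_gap_min = 12, stringsAsFactors = FALSE)
  recs <- run_cohort(manifest)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$case_id, "m1")
  expect_false(is.null(recs[[1]]$density_summary))
})
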