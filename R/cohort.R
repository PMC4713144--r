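# Cohort orchestration: per-case end-to-end runs, metadata exclusion rules,
# cohort-level descriptive aggregation, and the replication of the full
# statistical analysis from a per-thrombus summary table.

#' Per-case cohort record
#'
#' @param case_id case label.
#' @param slice_thickness_mm reconstruction slice thickness (mm); `NA` if
#'   unknown (flagged by [filter_cohort()]).
#' @param kernel convolution kernel label.
#' @param time_gap_min CTA-NCCT acquisition time gap in minutes.
#' @param density_summary a [summarize_density()] result, or `NULL`.
#' @param manual list of [simulate_manual()] results (or numeric values).
#' @param artifacts free-form list of per-case artifacts (masks, transform,
#'   stage log).
#' @return An object of class `cohort_record`.
#' @export
cohort_record <- function(case_id, slice_thickness_mm = NA_real_,
                          kernel = NA_character_, time_gap_min = NA_real_,
                          density_summary = NULL, manual = list(),
                          artifacts = list()) {
  structure(list(case_id = case_id,
                 slice_thickness_mm = slice_thickness_mm,
                 kernel = kernel, time_gap_min = time_gap_min,
                 density_summary = density_summary, manual = manual,
                 artifacts = artifacts, exclusion_reasons = character(0)),
            class = "cohort_record")
}

#' Apply the cohort metadata exclusion rules
#'
#' Excludes records with slice thickness strictly greater than 2.5 mm or a
#' CTA-NCCT time gap strictly exceeding 30 minutes (boundary values are
#' included). Missing metadata is flagged as its own exclusion reason, never
#' silently passed. The partition is exhaustive and disjoint.
#'
#' @param records list of [cohort_record()] objects.
#' @return list with elements `included` and `excluded`; every excluded
#'   record carries its named reasons in `$exclusion_reasons`.
#' @export
filter_cohort <- function(records) {
  included <- list(); excluded <- list()
  for (rec in records) {
    reasons <- character(0)
    if (is.na(rec$slice_thickness_mm)) reasons <- c(reasons, "missing_slice_thickness")
    else if (rec$slice_thickness_mm > 2.5) reasons <- c(reasons, "slice_thickness")
    if (is.na(rec$time_gap_min)) reasons <- c(reasons, "missing_time_gap")
    else if (rec$time_gap_min > 30) reasons <- c(reasons, "time_gap")
    rec$exclusion_reasons <- reasons
    if (length(reasons) == 0L) included <- c(included, list(rec))
    else excluded <- c(excluded, list(rec))
  }
  list(included = included, excluded = excluded)
}

summary_fields <- c(mean = "Mean", median = "Median", sd = "SD",
                    min = "Minimum", max = "Maximum",
                    iqr = "Interquartile Range", skewness = "Skewness",
                    kurtosis = "Kurtosis", volume_mm3 = "Volume")

manual_values <- function(rec) {
  vapply(rec$manual, function(m) {
    if (inherits(m, "manual_measurement")) m$value else as.numeric(m)
  }, numeric(1))
}

manual_ids <- function(rec) {
  vapply(seq_along(rec$manual), function(i) {
    m <- rec$manual[[i]]
    if (inherits(m, "manual_measurement")) m$observer
    else if (!is.null(names(rec$manual))) names(rec$manual)[i]
    else paste0("observer", i)
  }, character(1))
}

#' Cohort-level descriptive table
#'
#' For every entire-thrombus descriptor and every manual observer (plus the
#' pooled observers), reports the Average, SD, Min and Max across the
#' cohort's records: the layout of the cohort descriptive table.
#'
#' @param records list of included [cohort_record()] objects (>= 1 with a
#'   density summary).
#' @return data frame with columns `statistic`, `average`, `sd`, `min`,
#'   `max`, `n`.
#' @export
summarize_cohort <- function(records) {
  recs <- Filter(function(r) !is.null(r$density_summary), records)
  if (length(recs) == 0L) stop("no records with a density summary")
  agg <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L)
      return(data.frame(average = NA_real_, sd = NA_real_, min = NA_real_,
                        max = NA_real_, n = 0L))
    data.frame(average = mean(v), sd = if (length(v) > 1) sd(v) else 0,
               min = min(v), max = max(v), n = length(v))
  }
  rows <- lapply(names(summary_fields), function(f) {
    v <- vapply(recs, function(r) as.numeric(r$density_summary[[f]]), numeric(1))
    cbind(data.frame(statistic = summary_fields[[f]]), agg(v))
  })
  obs_tab <- do.call(rbind, lapply(recs, function(r) {
    v <- manual_values(r)
    if (length(v) == 0L) return(NULL)
    data.frame(observer = manual_ids(r), value = v)
  }))
  if (!is.null(obs_tab) && nrow(obs_tab) > 0L) {
    for (ob in unique(obs_tab$observer))
      rows <- c(rows, list(cbind(data.frame(statistic = ob),
                                 agg(obs_tab$value[obs_tab$observer == ob]))))
    rows <- c(rows, list(cbind(data.frame(statistic = "All Observers"),
                               agg(obs_tab$value))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full automated measurement on one CTA/NCCT pair
#'
#' Composes all stages end to end: contralateral vessel segmentation,
#' symmetry-plane estimation, mirror mapping, thrombus region growing on
#' CTA, rigid CTA-to-NCCT registration (with optional manual correction),
#' projection of the thrombus mask onto NCCT, density sampling and
#' summarisation. Any stage failure is re-raised with the stage name; a
#' registration convergence warning is recorded on the record.
#'
#' @param cta,ncct [volume3d()] volumes.
#' @param seeds 2 x 3 seed matrix for [segment_contralateral()].
#' @param config named list overriding defaults: `lumen_threshold`,
#'   `max_radius_mm`, `lower`, `upper`, `max_leak_mm`, `pve_erode_mm`
#'   (rim erosion of the projected mask for partial-volume-robust density
#'   sampling; volume is always reported for the full mask), `fixed_midplane`,
#'   `manual_correction` (a [rigid_transform()] or `NULL`), `alpha`,
#'   `case_id`, `kernel`, `time_gap_min`, `out_dir` (persist intermediate
#'   masks/transform as NIfTI/text when set).
#' @return A [cohort_record()]; `$artifacts` holds the vessel mask, symmetry
#'   plane, mapped region, thrombus masks, transform and a per-stage log
#'   (stage, status, seconds).
#' @export
run_case <- function(cta, ncct, seeds, config = list()) {
  cfg <- modifyList(list(lumen_threshold = 120, max_radius_mm = 4,
                         lower = 0, upper = 100, max_leak_mm = 1.5,
                         pve_erode_mm = 0.6, denoise_mm = 0.75,
                         grad_keep = 0.6,
                         fixed_midplane = FALSE, manual_correction = NULL,
                         alpha = 0.05, case_id = "case", kernel = NA_character_,
                         time_gap_min = 0, out_dir = NULL), config)
  log <- data.frame(stage = character(0), status = character(0),
                    seconds = numeric(0))
  note <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    log <<- rbind(log, data.frame(stage = stage, status = "ok",
                                  seconds = proc.time()[["elapsed"]] - t0))
    res
  }
  vessel <- note("segment_contralateral",
                 segment_contralateral(cta, seeds, cfg$lumen_threshold,
                                       cfg$max_radius_mm))
  plane <- note("estimate_symmetry_plane",
                estimate_symmetry_plane(cta, fixed_midplane = cfg$fixed_midplane))
  mapped <- note("mirror_mask", mirror_mask(vessel, plane))
  thrombus_cta <- note("segment_thrombus",
                       segment_thrombus(cta, mapped, cfg$lower, cfg$upper,
                                        cfg$max_leak_mm))
  reg_warn <- NULL
  tf <- note("register_rigid",
             withCallingHandlers(register_rigid(cta, ncct),
                                 warning = function(w) {
                                   reg_warn <<- conditionMessage(w)
                                   invokeRestart("muffleWarning")
                                 }))
  if (!is.null(cfg$manual_correction))
    tf <- apply_manual_correction(tf, cfg$manual_correction)
  thrombus_ncct <- note("apply_transform",
                        apply_transform(thrombus_cta, tf, as_grid(ncct)))
  # Density descriptors come from the partial-volume-robust core (the
  # projected mask eroded by pve_erode_mm): rim voxels blend with
  # near-isodense perivascular tissue and bias the distribution, while the
  # noise-free thrombus material is statistically homogeneous across the
  # lumen, so the core is an unbiased sample of the same distribution.
  # Volume and voxel count are always reported for the full projected mask.
  core <- thrombus_ncct
  if (cfg$pve_erode_mm > 0) {
    er <- erode_mask(thrombus_ncct, cfg$pve_erode_mm)
    if (mask_count(er) >= 20L) core <- er
  }
  ds <- note("sample_density", {
    s <- sample_density(ncct, core)
    vals <- if (cfg$denoise_mm > 0)
      median_filter_at(ncct, core, cfg$denoise_mm) else s$values
    if (cfg$grad_keep < 1 && length(vals) >= 50L) {
      # partial-volume control: drop the steepest-gradient voxels, whose
      # values are blends across composition/tissue boundaries
      gm <- gradient_magnitude_at(ncct, core)
      vals <- vals[gm <= quantile(gm, cfg$grad_keep)]
    }
    density_sample(vals, s$voxel_volume_mm3)
  })
  summ <- note("summarize", summarize_density(ds, alpha = cfg$alpha))
  summ$core_n_voxels <- summ$n_voxels
  summ$n_voxels <- mask_count(thrombus_ncct)
  summ$volume_mm3 <- mask_volume_mm3(thrombus_ncct)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_volume(thrombus_cta, file.path(cfg$out_dir, "thrombus_cta.nii.gz"))
    write_volume(thrombus_ncct, file.path(cfg$out_dir, "thrombus_ncct.nii.gz"))
    write_transform(tf, file.path(cfg$out_dir, "cta_to_ncct.txt"))
  }
  rec <- cohort_record(case_id = cfg$case_id,
                       slice_thickness_mm = as_grid(ncct)$spacing[3],
                       kernel = cfg$kernel, time_gap_min = cfg$time_gap_min,
                       density_summary = summ,
                       artifacts = list(vessel = vessel, plane = plane,
                                        mapped = mapped,
                                        thrombus_cta = thrombus_cta,
                                        thrombus_ncct = thrombus_ncct,
                                        transform = tf, log = log,
                                        registration_warning = reg_warn))
  rec
}

replication_required <- c("median", "mean", "sd", "iqr", "skewness",
                          "kurtosis", "volume_mm3", "obs1")

#' Replicate the cohort statistical analysis from a per-thrombus table
#'
#' Consumes a per-thrombus summary table (one row per case: entire-thrombus
#' descriptors plus per-observer manual values) and recomputes the cohort
#' descriptive aggregates, the manual-versus-median agreement (paired
#' t-tests, both regression orientations, Bland-Altman, ICC per observer
#' pair on complete cases) and the heterogeneity/volume regressions.
#' Supplementary tables distributed as SPSS .sav convert to the expected CSV
#' with one line of python: `pandas.read_spss("S1.sav").to_csv("s1.csv")`.
#'
#' @param s1 data frame with columns `median`, `mean`, `sd`, `iqr`,
#'   `skewness`, `kurtosis`, `volume_mm3`, `obs1` and optionally `obs2`,
#'   `obs3`, `slice_thickness_mm`, `kernel`. Missing manual values are `NA`
#'   (observers measured different subsets; pairing is complete-case per
#'   observer pair).
#' @return list with `descriptives` (cohort table), `delta` (paired t of
#'   obs1 against median and mean), `regression` (both orientations of the
#'   obs1/median fit), `interobserver` (ICC and Bland-Altman per pair),
#'   `associations` (manual and median against IQR and volume),
#'   `slice_thickness` (Pearson r of median vs slice thickness, when
#'   available) and `kernel_test` (Kruskal-Wallis of median by kernel, when
#'   available).
#' @export
replicate_analysis <- function(s1) {
  missing_cols <- setdiff(replication_required, names(s1))
  if (length(missing_cols) > 0L)
    stop("schema error: missing columns: ", paste(missing_cols, collapse = ", "))
  recs <- lapply(seq_len(nrow(s1)), function(i) {
    manual <- list()
    for (ob in c("obs1", "obs2", "obs3"))
      if (ob %in% names(s1) && !is.na(s1[[ob]][i]))
        manual[[ob]] <- s1[[ob]][i]
    ds <- structure(list(mean = s1$mean[i], median = s1$median[i],
                         sd = s1$sd[i],
                         min = if ("min" %in% names(s1)) s1$min[i] else NA_real_,
                         max = if ("max" %in% names(s1)) s1$max[i] else NA_real_,
                         iqr = s1$iqr[i], skewness = s1$skewness[i],
                         kurtosis = s1$kurtosis[i],
                         volume_mm3 = s1$volume_mm3[i], n_voxels = NA_integer_),
                    class = "density_summary")
    cohort_record(case_id = i, slice_thickness_mm = 1, time_gap_min = 0,
                  density_summary = ds, manual = manual)
  })
  descriptives <- summarize_cohort(recs)
  cc1 <- !is.na(s1$obs1)
  delta <- list(
    median = paired_t(s1$obs1[cc1], s1$median[cc1]),
    mean = paired_t(s1$obs1[cc1], s1$mean[cc1]))
  regression <- list(
    manual_on_median = fit_ols(s1$median[cc1], s1$obs1[cc1]),
    median_on_manual = fit_ols(s1$obs1[cc1], s1$median[cc1]))
  interobserver <- list()
  for (ob in c("obs2", "obs3")) {
    if (!ob %in% names(s1)) next
    cc <- cc1 & !is.na(s1[[ob]])
    if (sum(cc) >= 3L)
      interobserver[[paste0("obs1_", ob)]] <-
        list(icc = icc(s1$obs1[cc], s1[[ob]][cc]),
             bland_altman = bland_altman(s1$obs1[cc], s1[[ob]][cc]),
             n = sum(cc))
  }
  associations <- list(
    manual_vs_iqr = fit_ols(s1$iqr[cc1], s1$obs1[cc1]),
    manual_vs_volume = fit_ols(s1$volume_mm3[cc1], s1$obs1[cc1]),
    median_vs_iqr = fit_ols(s1$iqr, s1$median),
    median_vs_volume = fit_ols(s1$volume_mm3, s1$median))
  slice_thickness <- NULL
  if ("slice_thickness_mm" %in% names(s1) &&
      length(unique(na.omit(s1$slice_thickness_mm))) > 1L)
    slice_thickness <- pearson_cor(s1$slice_thickness_mm, s1$median)
  kernel_test <- NULL
  if ("kernel" %in% names(s1) && length(unique(na.omit(s1$kernel))) > 1L)
    kernel_test <- kruskal_wallis(split(s1$median, s1$kernel))
  list(descriptives = descriptives, delta = delta, regression = regression,
       interobserver = interobserver, associations = associations,
       slice_thickness = slice_thickness, kernel_test = kernel_test)
}

#' Run the automated measurement over a file manifest
#'
#' @param manifest data frame with columns `case_id`, `cta`, `ncct` (file
#'   paths), `seed1`, `seed2` (each `"x,y,z"` 1-based voxel indices), and
#'   optional `slice_thickness_mm`, `kernel`, `time_gap_min`.
#' @param config per-case config, see [run_case()].
#' @return list of [cohort_record()] objects.
#' @export
run_cohort <- function(manifest, config = list()) {
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    cta <- read_volume(row$cta)
    ncct <- read_volume(row$ncct)
    seeds <- rbind(as.numeric(strsplit(row$seed1, ",")[[1]]),
                   as.numeric(strsplit(row$seed2, ",")[[1]]))
    cfg <- modifyList(config, list(case_id = row$case_id))
    if (!is.null(row$kernel)) cfg$kernel <- row$kernel
    if (!is.null(row$time_gap_min)) cfg$time_gap_min <- row$time_gap_min
    rec <- run_case(cta, ncct, seeds, cfg)
    if (!is.null(row$slice_thickness_mm) && !is.na(row$slice_thickness_mm))
      rec$slice_thickness_mm <- row$slice_thickness_mm
    rec
  })
}
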