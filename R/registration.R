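# Rigid CTA-to-NCCT registration by mutual information, and the manual
# correction hook that replaces the interactive registration-repair step.

mutual_information <- function(hist) {
  p <- hist / sum(hist)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / (px[row(p)][nz] * py[col(p)][nz])))
}

mi_metric <- function(par, center, fixed_vals, fixed_pts, moving, rng, bins) {
  tf <- rigid_transform(rotation = par[1:3], translation = par[4:6],
                        center = center)
  q <- transform_points(tf, fixed_pts)
  idx <- world_to_index(moving, q)
  mv <- cpp_interp3(as.numeric(moving$voxels), as_grid(moving)$dim, idx,
                    rng$mmin, FALSE)
  h <- cpp_joint_hist(fixed_vals, mv, bins, rng$fmin, rng$fmax, rng$mmin,
                      rng$mmax)
  mutual_information(h)
}

#' Rigid registration of two volumes by mutual information
#'
#' Multi-resolution (4x, 2x, 1x block-mean pyramids) maximisation of the
#' joint-histogram mutual information (linear partial-volume binning, 32
#' bins) over the 6 rigid parameters, by Nelder-Mead. Mutual information
#' makes the metric multimodal-safe (contrast-enhanced CTA against NCCT). A
#' deterministic voxel subsample of the fixed volume is used at the finer
#' levels.
#'
#' @param moving,fixed [volume3d()] volumes; must be non-constant.
#' @param init optional initial [rigid_transform()].
#' @param bins number of histogram bins.
#' @param max_samples voxel sample cap per pyramid level.
#' @param seed seed for the deterministic voxel subsample.
#' @return A [rigid_transform()] mapping fixed-image world points into
#'   moving-image world space (use directly with [apply_transform()] to
#'   project moving-image masks onto the fixed grid). Attributes: `metric`
#'   (final mutual information), `metric_init` (at the initial transform),
#'   `converged` (logical; `FALSE` raises a convergence warning, mirroring
#'   the visual-inspection step of the original workflow).
#' @export
register_rigid <- function(moving, fixed, init = NULL, bins = 32L,
                           max_samples = 30000L, seed = 7L) {
  if (sd(moving$voxels) == 0 || sd(fixed$voxels) == 0)
    stop("degenerate-input error: constant volume cannot be registered")
  center <- grid_center(fixed)
  par <- c(0, 0, 0, 0, 0, 0)
  if (!is.null(init)) {
    af <- transform_affine(init)
    par <- c(euler_from_matrix(af$A),
             as.numeric(af$A %*% center) + af$b - center)
  }
  rng <- list(fmin = min(fixed$voxels), fmax = max(fixed$voxels),
              mmin = min(moving$voxels), mmax = max(moving$voxels))
  # parscale controls the initial Nelder-Mead simplex extent (deg / mm):
  # wide at the coarse level to cover the expected misalignment range,
  # narrow at the fine levels for sub-degree / sub-mm refinement.
  levels <- list(list(f = 4L, n = max_samples, maxit = 300L, restarts = 2L, scale = 15),
                 list(f = 2L, n = max_samples, maxit = 200L, restarts = 2L, scale = 4),
                 list(f = 1L, n = max_samples, maxit = 150L, restarts = 2L, scale = 1.5))
  par0 <- par
  for (li in seq_along(levels)) {
    lv <- levels[[li]]
    fx <- if (lv$f > 1L) downsample_volume(fixed, lv$f) else fixed
    mv <- if (lv$f > 1L) downsample_volume(moving, lv$f) else moving
    pts <- grid_points(fx)
    vals <- as.numeric(fx$voxels)
    if (length(vals) > lv$n) {
      keep <- with_seed(seed + li, sample.int(length(vals), lv$n))
      pts <- pts[keep, , drop = FALSE]
      vals <- vals[keep]
    }
    fn <- function(p) -mi_metric(p, center, vals, pts, mv, rng, bins)
    # Nelder-Mead restarts guard against premature simplex collapse
    for (r in seq_len(lv$restarts)) {
      opt <- optim(par, fn, method = "Nelder-Mead",
                   control = list(maxit = lv$maxit, reltol = 1e-10,
                                  parscale = rep(lv$scale, 6)))
      par <- opt$par
    }
  }
  # convergence judged at the finest level: the metric at the returned
  # transform must not fall below the metric at the initial transform
  metric_init <- -fn(par0)
  metric_final <- -fn(par)
  converged <- metric_final >= metric_init - 1e-12
  if (!converged)
    warning("registration convergence warning: metric did not improve; ",
            "returning best-found transform (consider apply_manual_correction)")
  out <- rigid_transform(rotation = par[1:3], translation = par[4:6],
                         center = center)
  attr(out, "metric") <- metric_final
  attr(out, "metric_init") <- metric_init
  attr(out, "converged") <- converged
  out
}

#' Apply a manual rigid correction to a registration result
#'
#' Returns the composition `correction` after `transform` (the hook standing
#' in for interactive registration repair): the corrected transform maps a
#' point `x` to `correction(transform(x))`.
#'
#' @param transform,correction [rigid_transform()] objects.
#' @export
apply_manual_correction <- function(transform, correction) {
  compose_transforms(correction, transform)
}
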