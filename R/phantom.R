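# Paired CTA/NCCT head phantoms with a bilaterally symmetric arterial tree,
# an occluding thrombus with a known (possibly non-normal) density
# distribution, CT noise, partial-volume blur, and a known rigid misalignment
# between the two scans. The phantom is the ground-truth test bed for every
# downstream stage of the pipeline.

#' Specification of a synthetic CTA/NCCT phantom pair
#'
#' The scene is defined analytically in world coordinates ("scene space",
#' which coincides with the CTA grid): an ellipsoidal head of brain
#' parenchyma in air, one contrast-enhanced artery per hemisphere (the
#' occluded-side artery is the exact mirror image of the contralateral
#' centerline about the midsagittal plane), and a thrombus occupying an arc
#' of the occluded-side vessel. Thrombus voxel densities follow a mixture of
#' normal components selected by a spatially smooth label field, so nearby
#' voxels share a component (locally coherent composition). The NCCT volume
#' is rendered at points pulled back through the misalignment transform, then
#' both volumes receive partial-volume blur and additive Gaussian noise.
#'
#' @param dim,spacing,origin grid geometry; slice spacing (third component)
#'   must be <= 2.5 mm, mirroring the cohort inclusion rule.
#' @param background_hu brain parenchyma attenuation (HU).
#' @param lumen_ncct_hu unenhanced blood attenuation on NCCT (HU).
#' @param head_semiaxes ellipsoid semi-axes of the head (mm).
#' @param centerline_mm control points (n x 3, mm) of the contralateral
#'   artery centerline, given in the half-space left of the symmetry plane.
#' @param vessel_radius vessel lumen radius (mm).
#' @param cta_enhancement added HU of contrast-enhanced lumen on CTA.
#' @param thrombus_arc start/end arc-length fractions (in `[0,1]`,
#'   start < end) of the thrombus along the occluded-side centerline.
#' @param thrombus_mix data frame with columns `weight`, `mean`, `sd`
#'   describing the thrombus density mixture; weights must sum to 1.
#' @param texture_scale_mm correlation length of the smooth component-label
#'   field (mm); scalar or length-3 (per axis, allowing patches elongated
#'   along the vessel axis).
#' @param noise_sd additive Gaussian CT noise (HU), >= 0.
#' @param blur_fwhm in-plane partial-volume blur FWHM (mm); when > 0 an
#'   additional slice-direction component with FWHM equal to the slice
#'   spacing is applied; 0 disables blur entirely.
#' @param misalignment a [rigid_transform()] mapping NCCT world points into
#'   scene (CTA) space, or `NULL` to draw one at generation time (uniform
#'   rotations within +-5 degrees and translations within +-5 mm).
#' @param seed integer seed controlling every random element of the phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(96, 96, 96),
                         spacing = c(0.5, 0.5, 0.5),
                         origin = c(0, 0, 0),
                         background_hu = 35,
                         lumen_ncct_hu = 40,
                         head_semiaxes = c(16, 22.5, 19),
                         centerline_mm = NULL,
                         vessel_radius = 2.4,
                         cta_enhancement = 165,
                         thrombus_arc = c(0.30, 0.66),
                         thrombus_mix = data.frame(weight = c(0.28, 0.44, 0.28),
                                                   mean = c(35, 45, 55),
                                                   sd = 2),
                         texture_scale_mm = c(Inf, Inf, 3.5),
                         noise_sd = 5,
                         blur_fwhm = 0.8,
                         misalignment = NULL,
                         seed = 1L) {
  grid <- grid3d(dim, spacing, origin)
  if (grid$spacing[3] > 2.5)
    stop("spec error: slice spacing must be <= 2.5 mm")
  if (abs(sum(thrombus_mix$weight) - 1) > 1e-8)
    stop("spec error: mixture weights must sum to 1")
  if (any(thrombus_mix$sd < 0)) stop("spec error: mixture SDs must be >= 0")
  if (length(thrombus_arc) != 2L || thrombus_arc[1] < 0 ||
      thrombus_arc[2] > 1 || thrombus_arc[1] >= thrombus_arc[2])
    stop("spec error: thrombus arc fractions must satisfy 0 <= start < end <= 1")
  if (noise_sd < 0) stop("spec error: noise SD must be >= 0")
  center <- grid_center(grid)
  if (is.null(centerline_mm)) {
    # carotid/M1-like gently curved course in the left hemisphere
    span <- (grid$dim - 1) * grid$spacing
    z <- origin[3] + span[3] * c(0.22, 0.34, 0.48, 0.64, 0.78)
    centerline_mm <- cbind(
      center[1] - c(9.5, 10.5, 10.0, 8.5, 9.5),
      center[2] + c(0.5, 1.5, 3.0, 1.0, -1.5),
      z)
  }
  if (any(centerline_mm[, 1] >= center[1]))
    stop("spec error: centerline control points must lie left of the symmetry plane")
  structure(list(grid = grid, background_hu = background_hu,
                 lumen_ncct_hu = lumen_ncct_hu, head_semiaxes = head_semiaxes,
                 centerline_mm = centerline_mm, vessel_radius = vessel_radius,
                 cta_enhancement = cta_enhancement, thrombus_arc = thrombus_arc,
                 thrombus_mix = thrombus_mix,
                 texture_scale_mm = texture_scale_mm, noise_sd = noise_sd,
                 blur_fwhm = blur_fwhm, misalignment = misalignment,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Smooth stationary Gaussian random field (unit marginal variance) via random
# Fourier features; returns a closure evaluable at any n x 3 world point set.
# Deterministic given the RNG state at call time.
rff_field <- function(scale_mm, K = 96L) {
  scale_mm <- rep(scale_mm, length.out = 3L)
  W <- cbind(rnorm(K, sd = 1 / scale_mm[1]), rnorm(K, sd = 1 / scale_mm[2]),
             rnorm(K, sd = 1 / scale_mm[3]))
  phase <- runif(K, 0, 2 * pi)
  amp <- sqrt(2 / K)
  function(pts) {
    g <- numeric(nrow(pts))
    for (i in seq_len(K))
      g <- g + cos(pts %*% W[i, ] + phase[i])
    amp * as.numeric(g)
  }
}

# Per-point thrombus HU field: a smooth label field picks the mixture
# component, a second smooth field supplies the within-component variate.
# The label field is rank-transformed over a reference point set (the
# thrombus voxels on the scene grid) so component occupancies match the
# mixture weights exactly rather than fluctuating with the random field:
# a thrombus of a few hundred voxels holds only a handful of independent
# texture patches, far too few for raw occupancies to concentrate.
thrombus_field <- function(mix, scale_mm, ref_pts) {
  g <- rff_field(scale_mm)
  # within-component variate: shorter-scale than the label field along each
  # finite axis (a patch-constant variate would collapse the empirical
  # quantiles onto a few plateaus), but sharing the label field's in-plane
  # uniformity so cross-section sampling effects stay component-neutral
  h <- rff_field(ifelse(is.finite(scale_mm), pmax(scale_mm * 0.45, 1), Inf))
  cw <- cumsum(mix$weight)
  ref <- sort(g(ref_pts))
  n <- length(ref)
  function(pts) {
    u <- (findInterval(g(pts), ref) + 0.5) / (n + 1)
    comp <- findInterval(u, cw, rightmost.closed = TRUE) + 1L
    comp[comp > nrow(mix)] <- nrow(mix)
    mix$mean[comp] + mix$sd[comp] * h(pts)
  }
}

# Dense centerline polyline through the control points (natural splines per
# coordinate), plus its mirror image about the vertical plane x = cx.
dense_centerline <- function(ctrl, n = 250L) {
  t0 <- seq_len(nrow(ctrl))
  tt <- seq(1, nrow(ctrl), length.out = n)
  cbind(spline(t0, ctrl[, 1], xout = tt)$y,
        spline(t0, ctrl[, 2], xout = tt)$y,
        spline(t0, ctrl[, 3], xout = tt)$y)
}

mirror_polyline <- function(poly, cx) cbind(2 * cx - poly[, 1], poly[, 2:3])

# Distance/arc-fraction to a polyline with a bounding-box prefilter; points
# outside the box get +Inf distance.
polyline_distance <- function(pts, poly, margin) {
  lo <- apply(poly, 2, min) - margin
  hi <- apply(poly, 2, max) + margin
  cand <- pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
    pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
    pts[, 3] >= lo[3] & pts[, 3] <= hi[3]
  dist <- rep(Inf, nrow(pts))
  frac <- rep(NA_real_, nrow(pts))
  if (any(cand)) {
    r <- cpp_dist_polyline(pts[cand, , drop = FALSE], poly)
    dist[cand] <- r$dist
    frac[cand] <- r$frac
  }
  list(dist = dist, frac = frac)
}

# Noiseless, unblurred scene evaluation at arbitrary world points.
# Returns HU for the requested modality plus geometric labels.
eval_scene <- function(pts, spec, polyL, polyR, thr_fun, modality) {
  center <- grid_center(spec$grid)
  r <- spec$vessel_radius
  e <- sweep(sweep(pts, 2, center, "-"), 2, spec$head_semiaxes, "/")
  in_head <- rowSums(e^2) <= 1
  dL <- polyline_distance(pts, polyL, r + 1)
  dR <- polyline_distance(pts, polyR, r + 1)
  lumenL <- in_head & dL$dist <= r
  in_tubeR <- in_head & dR$dist <= r
  thr <- in_tubeR & !is.na(dR$frac) &
    dR$frac >= spec$thrombus_arc[1] & dR$frac <= spec$thrombus_arc[2]
  lumenR <- in_tubeR & !thr
  hu <- rep(-1000, nrow(pts))
  hu[in_head] <- spec$background_hu
  lumen_hu <- if (modality == "cta")
    spec$background_hu + spec$cta_enhancement else spec$lumen_ncct_hu
  hu[lumenL | lumenR] <- lumen_hu
  if (any(thr) && !is.null(thr_fun)) hu[thr] <- thr_fun(pts[thr, , drop = FALSE])
  list(hu = hu, thrombus = thr, lumenL = lumenL, occluded_tree = in_tubeR)
}

blur_sigmas_vox <- function(spec) {
  if (spec$blur_fwhm <= 0) return(c(0, 0, 0))
  s_iso <- spec$blur_fwhm / (2 * sqrt(2 * log(2)))
  s_slice <- spec$grid$spacing[3] / (2 * sqrt(2 * log(2)))
  c(s_iso, s_iso, sqrt(s_iso^2 + s_slice^2)) / spec$grid$spacing
}

finish_volume <- function(hu, spec, noise_stream_offset) {
  g <- spec$grid
  a <- array(hu, dim = g$dim)
  sig <- blur_sigmas_vox(spec)
  if (any(sig > 0)) a <- array(cpp_blur_sep(as.numeric(a), g$dim, sig), dim = g$dim)
  if (spec$noise_sd > 0)
    a <- a + array(rnorm(length(a), sd = spec$noise_sd), dim = g$dim)
  volume3d(a, g$spacing, g$origin)
}

#' Generate a paired CTA/NCCT phantom with ground truth
#'
#' Fully deterministic given `spec$seed`: the same spec yields bit-identical
#' volumes. See [phantom_spec()] for the scene model.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `cta` and `ncct` ([volume3d()]) and `truth`,
#'   itself a list with: `thrombus_cta` and `thrombus_ncct`
#'   ([voxel_mask()]s on the two grids), `contralateral` and `occluded_tree`
#'   masks on the CTA grid, `misalignment` (the realised
#'   [rigid_transform()], NCCT world -> scene/CTA world), `plane` (the true
#'   [symmetry_plane()]), `thrombus_hu` (noiseless per-voxel HU of the NCCT
#'   thrombus voxels, in column-major mask order), `density_summary` (the
#'   true [summarize_density()] of those values) and `seeds` (a proximal /
#'   distal voxel pair on the contralateral artery, 1-based indices).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  center <- grid_center(g)
  with_seed(spec$seed, {
    mis <- spec$misalignment
    if (is.null(mis))
      mis <- rigid_transform(rotation = runif(3, -5, 5),
                             translation = runif(3, -5, 5),
                             center = center)
    polyL <- dense_centerline(spec$centerline_mm)
    polyR <- mirror_polyline(polyL, center[1])

    pts <- grid_points(g)
    sc_geom <- eval_scene(pts, spec, polyL, polyR, NULL, "cta")
    if (!any(sc_geom$thrombus))
      stop("spec error: thrombus arc lies outside the vessel extent")
    thr_fun <- thrombus_field(spec$thrombus_mix, spec$texture_scale_mm,
                              pts[sc_geom$thrombus, , drop = FALSE])
    sc_cta <- eval_scene(pts, spec, polyL, polyR, thr_fun, "cta")
    cta <- finish_volume(sc_cta$hu, spec, 1L)

    q <- transform_points(mis, pts)  # NCCT voxel centres pulled into scene space
    sc_ncct <- eval_scene(q, spec, polyL, polyR, thr_fun, "ncct")
    ncct <- finish_volume(sc_ncct$hu, spec, 2L)

    seeds_world <- polyL[round(c(0.08, 0.92) * (nrow(polyL) - 1)) + 1L, ]
    seeds <- round(world_to_index(g, seeds_world)) + 1L

    thr_mask_ncct <- voxel_mask(array(sc_ncct$thrombus, dim = g$dim), g)
    thr_hu <- sc_ncct$hu[sc_ncct$thrombus]
    truth <- list(
      thrombus_cta = voxel_mask(array(sc_cta$thrombus, dim = g$dim), g),
      thrombus_ncct = thr_mask_ncct,
      contralateral = voxel_mask(array(sc_cta$lumenL, dim = g$dim), g),
      occluded_tree = voxel_mask(array(sc_cta$occluded_tree, dim = g$dim), g),
      misalignment = mis,
      plane = symmetry_plane(point = center, normal = c(1, 0, 0)),
      thrombus_hu = thr_hu,
      density_summary = summarize_density(
        density_sample(thr_hu, prod(g$spacing))),
      seeds = seeds)
    list(cta = cta, ncct = ncct, truth = truth)
  })
}

# Split a target IQR into lower/upper component offsets around the median,
# keeping component means inside the physiological window [10, 72] HU.
# Weights put just over half the mass in the middle component (median pinned
# there, with a sharp empirical density around it); the quartiles sit inside
# the outer components.
realize_mixture <- function(median_hu, iqr_hu, sd = 2, lo = 10, hi = 72,
                            weights = c(0.28, 0.44, 0.28)) {
  # type-7 quartiles of the realised mixture sit ~ sd * qnorm(0.25/w1)
  # inside the outer components; widen the split so the realised IQR
  # matches the target
  w <- iqr_hu + 2 * sd * qnorm(0.25 / weights[1])
  a <- b <- w / 2
  over <- max(0, a - (median_hu - lo))
  a <- a - over; b <- b + over
  over <- max(0, b - (hi - median_hu))
  b <- b - over; a <- a + over
  a <- min(a, median_hu - lo)
  data.frame(weight = weights,
             mean = c(median_hu - a, median_hu, median_hu + b),
             sd = sd)
}

#' Sample a cohort of phantom specifications
#'
#' Draws `n` phantom specs whose target thrombus medians are uniform on
#' [20, 64] HU and target IQRs uniform on [9, 56] HU, mirroring the spread of
#' the measured cohort. Targets are realised as three-component mixtures
#' (weights 0.3/0.4/0.3) whose outer component means are capped to a
#' physiological window of 10-72 HU; the realised per-phantom ground truth is
#' always the empirical summary stored in the phantom truth record. Each spec
#' carries its own seed and a random misalignment; everything is
#' deterministic given `seed`.
#'
#' @param n number of specs, >= 1.
#' @param seed integer seed.
#' @param ... further arguments passed to [phantom_spec()] (e.g. a smaller
#'   grid for quick tests).
#' @return A list of `n` [phantom_spec()] objects; each has attributes
#'   `target_median` and `target_iqr`.
#' @export
sample_cohort_specs <- function(n, seed = 1L, ...) {
  stopifnot(n >= 1)
  with_seed(seed, {
    med <- runif(n, 20, 64)
    iqr <- runif(n, 9, 56)
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      sp <- phantom_spec(thrombus_mix = realize_mixture(med[i], iqr[i]),
                         seed = sub_seeds[i], ...)
      attr(sp, "target_median") <- med[i]
      attr(sp, "target_iqr") <- iqr[i]
      sp
    })
  })
}
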