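# Step (1) of the automated method: segmentation of the patent,
# contrast-enhanced contralateral artery on CTA from two manually placed
# seed points.

#' Segment the contralateral artery on CTA from two seed points
#'
#' Threshold-constrained region growing (26-connectivity) from a proximal and
#' a distal seed, intersected with a geodesic tube: the minimal path between
#' the seeds through the above-threshold region is computed (Dijkstra, world
#' metric) and voxels farther than `max_radius_mm` from that path are
#' discarded. The tube prevents leakage into bone or adjacent vessels while
#' keeping the full lumen between the seeds.
#'
#' @param cta a [volume3d()] CT angiography volume.
#' @param seeds 2 x 3 matrix of 1-based voxel indices (proximal, distal) on
#'   the contralateral artery; both must be above `lumen_threshold`.
#' @param lumen_threshold HU threshold separating enhancing lumen from
#'   thrombus and parenchyma (default 120 HU).
#' @param max_radius_mm maximal distance (mm) from the seed-to-seed path.
#' @return A [voxel_mask()] containing both seeds, only above-threshold
#'   voxels, and a connecting path.
#' @export
segment_contralateral <- function(cta, seeds, lumen_threshold = 120,
                                  max_radius_mm = 4) {
  g <- as_grid(cta)
  seeds <- matrix(as.integer(round(seeds)), ncol = 3)
  if (nrow(seeds) != 2L) stop("seed error: exactly two seed points required")
  if (any(seeds < 1L) || any(sweep(seeds, 2, g$dim, ">") ))
    stop("seed error: seed outside the volume")
  seed_vals <- cta$voxels[seeds]
  if (any(seed_vals < lumen_threshold))
    stop(sprintf("seed error: seed HU (%s) below lumen threshold %g",
                 paste(round(seed_vals, 1), collapse = ", "), lumen_threshold))
  allowed <- as.logical(cta$voxels >= lumen_threshold)
  lin0 <- (seeds[, 1] - 1L) + (seeds[, 2] - 1L) * g$dim[1] +
    (seeds[, 3] - 1L) * g$dim[1] * g$dim[2]
  grown <- cpp_region_grow(g$dim, allowed, lin0)
  path <- cpp_shortest_path(g$dim, allowed, lin0[1], lin0[2], g$spacing)
  if (length(path) == 0L)
    stop("connectivity error: no above-threshold path joins the seeds")
  # geodesic tube constraint around the minimal path
  path_idx0 <- cbind(path %% g$dim[1],
                     (path %/% g$dim[1]) %% g$dim[2],
                     path %/% (g$dim[1] * g$dim[2]))
  path_world <- index_to_world(g, path_idx0)
  grown_lin0 <- which(grown) - 1L
  grown_idx0 <- cbind(grown_lin0 %% g$dim[1],
                      (grown_lin0 %/% g$dim[1]) %% g$dim[2],
                      grown_lin0 %/% (g$dim[1] * g$dim[2]))
  d <- cpp_dist_polyline(index_to_world(g, grown_idx0), path_world)$dist
  keep <- logical(length(allowed))
  keep[grown_lin0[d <= max_radius_mm] + 1L] <- TRUE
  voxel_mask(array(keep, dim = g$dim), g)
}
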