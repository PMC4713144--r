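# Step (2) of the automated method: estimate the midsagittal symmetry plane
# and map the contralateral vessel segmentation onto the occluded side by
# mirror symmetry.

#' Midsagittal symmetry plane
#'
#' A plane in world coordinates given by a point on the plane and a unit
#' normal. The reflection of a point `p` is `p - 2 ((p - point) . n) n`.
#'
#' @param point numeric length-3, a point on the plane (mm).
#' @param normal numeric length-3; normalised to unit length.
#' @return An object of class `symmetry_plane`.
#' @export
symmetry_plane <- function(point, normal) {
  nrm <- sqrt(sum(normal^2))
  if (nrm == 0) stop("plane normal must be non-zero")
  structure(list(point = as.numeric(point), normal = as.numeric(normal) / nrm),
            class = "symmetry_plane")
}

#' @export
print.symmetry_plane <- function(x, ...) {
  cat(sprintf("symmetry_plane: point (%.2f, %.2f, %.2f) mm, normal (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Reflect world points about a symmetry plane
#' @param plane a [symmetry_plane()].
#' @param pts n x 3 matrix of world points (mm).
#' @export
reflect_points <- function(plane, pts) {
  s <- as.numeric(pts %*% plane$normal) - sum(plane$point * plane$normal)
  pts - 2 * outer(s, plane$normal)
}

# plane from (tilt about y, tilt about z, offset along the tilted normal),
# relative to the grid centre and the +x axis.
plane_from_params <- function(theta_deg, center) {
  n <- as.numeric(rotation_matrix(c(0, theta_deg[1], theta_deg[2])) %*% c(1, 0, 0))
  symmetry_plane(point = center + theta_deg[3] * n, normal = n)
}

# Normalised cross-correlation between a volume and its reflection about the
# plane, over voxels whose reflections stay inside the grid.
reflection_ncc <- function(volume, plane, pts = NULL, vals = NULL) {
  if (is.null(pts)) pts <- grid_points(volume)
  if (is.null(vals)) vals <- as.numeric(volume$voxels)
  ref <- reflect_points(plane, pts)
  idx <- world_to_index(volume, ref)
  rv <- cpp_interp3(as.numeric(volume$voxels), as_grid(volume)$dim, idx,
                    NA_real_, FALSE)
  ok <- !is.na(rv)
  if (sum(ok) < 10) return(-Inf)
  a <- vals[ok]; b <- rv[ok]
  sa <- sd(a); sb <- sd(b)
  if (sa == 0 || sb == 0) return(-Inf)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

#' Estimate the midsagittal symmetry plane of a head volume
#'
#' Finds the plane maximising the normalised cross-correlation (NCC) between
#' the volume and its reflection. The plane is parameterised by two tilt
#' angles of the normal away from the first (left-right) axis plus an offset
#' along the normal through the volume centre. A coarse grid search
#' (+-10 degrees, +-10 mm) on a 4x downsampled copy is refined by
#' Nelder-Mead on a 2x downsampled copy.
#'
#' @param volume a [volume3d()] with at least 2 voxels along each axis.
#' @param initial_guess optional [symmetry_plane()] used as an extra starting
#'   candidate; the returned plane never scores below it.
#' @param fixed_midplane if `TRUE`, skip estimation and return the central
#'   sagittal plane of the grid.
#' @return A [symmetry_plane()] with attribute `ncc` (the objective value).
#' @export
estimate_symmetry_plane <- function(volume, initial_guess = NULL,
                                    fixed_midplane = FALSE) {
  g <- as_grid(volume)
  if (any(g$dim < 2L)) stop("volume must have >= 2 voxels along each axis")
  center <- grid_center(g)
  if (fixed_midplane)
    return(symmetry_plane(point = center, normal = c(1, 0, 0)))
  if (sd(volume$voxels) == 0)
    stop("degenerate-input error: constant volume has no symmetry plane")
  v4 <- downsample_volume(volume, pmax(1L, g$dim %/% 24L))
  pts4 <- grid_points(v4); vals4 <- as.numeric(v4$voxels)
  if (length(vals4) > 8000L) {
    keep <- with_seed(11L, sample.int(length(vals4), 8000L))
    pts4 <- pts4[keep, , drop = FALSE]; vals4 <- vals4[keep]
  }
  obj4 <- function(p) reflection_ncc(v4, plane_from_params(p, center), pts4, vals4)
  cand <- expand.grid(ty = seq(-10, 10, by = 2.5),
                      tz = seq(-10, 10, by = 2.5),
                      off = seq(-10, 10, by = 2.5))
  scores <- apply(cand, 1, function(p) obj4(as.numeric(p)))
  best <- as.numeric(cand[which.max(scores), ])
  # refinement at 2x downsampling
  v2 <- downsample_volume(volume, pmax(1L, g$dim %/% 48L))
  pts2 <- grid_points(v2); vals2 <- as.numeric(v2$voxels)
  if (length(vals2) > 20000L) {
    keep <- with_seed(12L, sample.int(length(vals2), 20000L))
    pts2 <- pts2[keep, , drop = FALSE]; vals2 <- vals2[keep]
  }
  obj2 <- function(p) -reflection_ncc(v2, plane_from_params(p, center), pts2, vals2)
  opt <- optim(best, obj2, method = "Nelder-Mead",
               control = list(maxit = 300, reltol = 1e-10))
  par <- opt$par; score <- -opt$value
  if (!is.null(initial_guess)) {
    init_score <- reflection_ncc(v2, initial_guess, pts2, vals2)
    if (init_score > score)
      return(structure(initial_guess, ncc = init_score))
  }
  structure(plane_from_params(par, center), ncc = score)
}

#' Reflect a volume about a symmetry plane
#'
#' Resamples the volume at the reflections of its own voxel centres. With
#' nearest-neighbour interpolation (the default, appropriate for label maps
#' and for exact involution on lattice-aligned planes) reflecting twice
#' returns the original array.
#'
#' @param volume a [volume3d()].
#' @param plane a [symmetry_plane()].
#' @param interp `"nearest"` or `"linear"`.
#' @param fill value for reflections leaving the grid.
#' @export
reflect_volume <- function(volume, plane, interp = c("nearest", "linear"),
                           fill = min(volume$voxels)) {
  interp <- match.arg(interp)
  g <- as_grid(volume)
  idx <- world_to_index(g, reflect_points(plane, grid_points(g)))
  v <- cpp_interp3(as.numeric(volume$voxels), g$dim, idx, fill,
                   interp == "nearest")
  volume3d(array(v, dim = g$dim), g$spacing, g$origin, volume$axes)
}

#' Mirror a mask about the symmetry plane
#'
#' Maps the contralateral vessel segmentation onto the occluded side: each
#' target voxel is foreground when the source mask is foreground at the
#' nearest voxel to the reflection of its centre.
#'
#' @param mask a non-empty [voxel_mask()].
#' @param plane a [symmetry_plane()].
#' @return A [voxel_mask()] on the same grid.
#' @export
mirror_mask <- function(mask, plane) {
  if (mask_count(mask) == 0L) stop("mask is empty")
  g <- mask$grid
  idx <- world_to_index(g, reflect_points(plane, grid_points(g)))
  v <- cpp_interp3(as.numeric(mask$mask), g$dim, idx, 0, TRUE)
  out <- voxel_mask(array(v > 0.5, dim = g$dim), g)
  if (mask_count(out) == 0L)
    stop("empty-result error: reflection falls entirely outside the grid")
  out
}
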