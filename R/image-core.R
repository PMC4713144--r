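#' Spatial grid descriptor
#'
#' A grid is the geometry of a voxel lattice: array dimensions, voxel spacing
#' in mm, and the world position (mm) of the first voxel centre. All geometry
#' in the package is computed in world coordinates: the centre of voxel
#' `(i, j, k)` (0-based) lies at `origin + c(i, j, k) * spacing`. Axes are
#' treated as axis-aligned; the first axis is the nominal left-right axis.
#'
#' @param dim integer length-3 array dimensions.
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin numeric length-3, world coordinates (mm) of voxel (0,0,0).
#' @return An object of class `grid3d`.
#' @export
grid3d <- function(dim, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  dim <- as.integer(dim)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(dim) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(dim < 1L)) stop("grid dimensions must be >= 1")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("metadata error: spacing components must be finite and > 0")
  structure(list(dim = dim, spacing = spacing, origin = origin),
            class = "grid3d")
}

#' 3D scalar volume of Hounsfield units
#'
#' @param voxels 3D numeric array of HU values (finite).
#' @param spacing,origin grid geometry, see [grid3d()].
#' @param axes character length-3 orientation labels (informational).
#' @return An object of class `volume3d` with fields `voxels`, `spacing`,
#'   `origin`, `axes`.
#' @export
volume3d <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     axes = c("x", "y", "z")) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (length(voxels) == 0L) stop("voxel array is empty")
  if (any(!is.finite(voxels))) stop("HU values must be finite")
  g <- grid3d(dim(voxels), spacing, origin)
  structure(list(voxels = voxels, spacing = g$spacing, origin = g$origin,
                 axes = axes),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("volume3d %s, spacing %s mm, origin %s mm, HU range [%.1f, %.1f]\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", "),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary voxel mask on a reference grid
#'
#' @param mask logical (or 0/1) 3D array.
#' @param grid the [grid3d()] of the volume the mask indexes. May be a
#'   `volume3d`, in which case its grid is taken.
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(mask, grid) {
  grid <- as_grid(grid)
  m <- array(as.logical(mask), dim = dim(mask))
  if (!identical(as.integer(dim(m)), grid$dim))
    stop("mask shape does not match its reference grid")
  structure(list(mask = m, grid = grid), class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("voxel_mask %s, %d foreground voxels, %.1f mm^3\n",
              paste(x$grid$dim, collapse = "x"), mask_count(x),
              mask_volume_mm3(x)))
  invisible(x)
}

#' @rdname voxel_mask
#' @param x a `voxel_mask`.
#' @export
mask_count <- function(x) sum(x$mask)

#' Physical mask volume in cubic millimetres
#'
#' Foreground voxel count times the voxel volume (product of the grid
#' spacing components).
#' @param x a `voxel_mask`.
#' @export
mask_volume_mm3 <- function(x) sum(x$mask) * prod(x$grid$spacing)

as_grid <- function(x) {
  if (inherits(x, "grid3d")) return(x)
  if (inherits(x, "volume3d")) return(grid3d(dim(x$voxels), x$spacing, x$origin))
  if (inherits(x, "voxel_mask")) return(x$grid)
  stop("cannot interpret object as a grid")
}

# World coordinates (n x 3, mm) of every voxel centre, column-major order.
grid_points <- function(grid) {
  grid <- as_grid(grid)
  d <- grid$dim
  i <- rep.int(seq_len(d[1]) - 1L, d[2] * d[3])
  j <- rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3])
  k <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  cbind(grid$origin[1] + i * grid$spacing[1],
        grid$origin[2] + j * grid$spacing[2],
        grid$origin[3] + k * grid$spacing[3])
}

# Continuous 0-based index coordinates of world points on a grid.
world_to_index <- function(grid, pts) {
  grid <- as_grid(grid)
  cbind((pts[, 1] - grid$origin[1]) / grid$spacing[1],
        (pts[, 2] - grid$origin[2]) / grid$spacing[2],
        (pts[, 3] - grid$origin[3]) / grid$spacing[3])
}

index_to_world <- function(grid, idx0) {
  grid <- as_grid(grid)
  cbind(grid$origin[1] + idx0[, 1] * grid$spacing[1],
        grid$origin[2] + idx0[, 2] * grid$spacing[2],
        grid$origin[3] + idx0[, 3] * grid$spacing[3])
}

# World centre of the grid's bounding box.
grid_center <- function(grid) {
  grid <- as_grid(grid)
  grid$origin + (grid$dim - 1) * grid$spacing / 2
}

#' Resample a volume onto a target grid
#'
#' The value at each target voxel centre `p` is taken from the source volume
#' at `transform(p)` (a pull-back, as in ITK: the transform maps target/fixed
#' world points to source/moving world points). Linear interpolation for
#' volumes; use [apply_transform()] for masks.
#'
#' @param volume a [volume3d()].
#' @param target_grid a [grid3d()] (or object with a grid).
#' @param transform a [rigid_transform()]; identity if `NULL`.
#' @param interp `"linear"` or `"nearest"`.
#' @param fill value for points mapping outside the source grid.
#' @export
resample_volume <- function(volume, target_grid, transform = NULL,
                            interp = c("linear", "nearest"), fill = min(volume$voxels)) {
  interp <- match.arg(interp)
  tg <- as_grid(target_grid)
  pts <- grid_points(tg)
  if (!is.null(transform)) pts <- transform_points(transform, pts)
  idx <- world_to_index(volume, pts)
  v <- cpp_interp3(as.numeric(volume$voxels), as_grid(volume)$dim, idx,
                   fill, interp == "nearest")
  volume3d(array(v, dim = tg$dim), tg$spacing, tg$origin, volume$axes)
}

#' Project a mask through a rigid transform onto a target grid
#'
#' Nearest-neighbour resampling of a binary mask: target voxel `p` is
#' foreground when the source mask is foreground at the voxel nearest to
#' `transform(p)`. Used to project the CTA-based thrombus segmentation onto
#' the NCCT grid after registration.
#'
#' @param mask a non-empty [voxel_mask()].
#' @param transform a [rigid_transform()] mapping target world points into the
#'   mask's world space.
#' @param target_grid grid to resample onto.
#' @return A [voxel_mask()] on `target_grid`.
#' @export
apply_transform <- function(mask, transform, target_grid) {
  if (mask_count(mask) == 0L) stop("mask is empty")
  tg <- as_grid(target_grid)
  pts <- transform_points(transform, grid_points(tg))
  idx <- world_to_index(mask$grid, pts)
  v <- cpp_interp3(as.numeric(mask$mask), mask$grid$dim, idx, 0, TRUE)
  out <- voxel_mask(array(v > 0.5, dim = tg$dim), tg)
  if (mask_count(out) == 0L)
    stop("empty-result error: transform maps the mask outside the target grid")
  out
}

# Downsampled copy of a volume (block mean, integer factor per axis).
downsample_volume <- function(volume, factor) {
  f <- as.integer(rep(factor, length.out = 3))
  f <- pmax(1L, pmin(f, as_grid(volume)$dim))
  r <- cpp_downsample(as.numeric(volume$voxels), as_grid(volume)$dim, f)
  volume3d(array(r$vox, dim = r$dim), volume$spacing * f,
           volume$origin + (f - 1) * volume$spacing / 2, volume$axes)
}

#' Dice overlap coefficient between two masks on the same grid
#' @param a,b `voxel_mask` objects with identical grids.
#' @export
dice <- function(a, b) {
  stopifnot(identical(a$grid$dim, b$grid$dim))
  2 * sum(a$mask & b$mask) / (sum(a$mask) + sum(b$mask))
}

#' Dilate or erode a mask by a physical radius
#' @param mask a `voxel_mask`.
#' @param radius_mm radius in mm (ellipsoidal structuring element in voxel
#'   space, spacing-aware).
#' @export
dilate_mask <- function(mask, radius_mm) {
  g <- mask$grid
  m <- cpp_dilate(g$dim, as.logical(mask$mask), g$spacing, radius_mm)
  voxel_mask(array(m, dim = g$dim), g)
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, radius_mm) {
  g <- mask$grid
  dil <- cpp_dilate(g$dim, as.logical(!mask$mask), g$spacing, radius_mm)
  voxel_mask(array(!dil & mask$mask, dim = g$dim), g)
}

# Largest 26-connected component of a mask; ties broken by higher mean value
# of `tie_values` (a numeric array on the same grid) when supplied.
largest_component <- function(mask, tie_values = NULL) {
  g <- mask$grid
  lab <- cpp_label_components(g$dim, as.logical(mask$mask))
  if (all(lab == 0L)) return(mask)
  sizes <- tabulate(lab)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L && !is.null(tie_values)) {
    mhu <- vapply(best, function(b) mean(tie_values[lab == b]), numeric(1))
    best <- best[which.max(mhu)]
  } else best <- best[1]
  voxel_mask(array(lab == best, dim = g$dim), g)
}
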