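# Step (3) of the automated method: intensity-based region growing of the
# thrombus on CTA within the symmetry-mapped occluded-artery region.

#' Segment the thrombus within the mapped occluded-artery region
#'
#' Seeds are all voxels of `mapped_region` whose CTA value lies in
#' `[lower, upper]`. Growth proceeds with 26-connectivity through a corridor
#' obtained by dilating `mapped_region` by `max_leak_mm` (absorbing
#' symmetry-mapping error while bounding leakage), restricted to the
#' intensity window. The final mask is the largest connected component of
#' the grown region intersected with the undilated `mapped_region`: voxels
#' of perivascular tissue, which is nearly isodense with thrombus, would
#' otherwise enter through the dilation ring and bias the density
#' distribution. The upper bound excludes contrast-enhancing (patent lumen /
#' stagnant blood) voxels by construction.
#'
#' @param cta a [volume3d()].
#' @param mapped_region non-empty [voxel_mask()] from [mirror_mask()].
#' @param lower,upper HU window for thrombus voxels, `lower < upper`
#'   (defaults 0 and 100: excludes air/fat below and contrast above).
#' @param max_leak_mm dilation radius (mm) of the growth corridor.
#' @return A [voxel_mask()]; ties between equally large components are broken
#'   towards higher mean HU.
#' @export
segment_thrombus <- function(cta, mapped_region, lower = 0, upper = 100,
                             max_leak_mm = 1.5) {
  if (mask_count(mapped_region) == 0L) stop("mapped region is empty")
  stopifnot(lower < upper)
  g <- as_grid(cta)
  stopifnot(identical(g$dim, mapped_region$grid$dim))
  in_window <- cta$voxels >= lower & cta$voxels <= upper
  seeds_arr <- mapped_region$mask & in_window
  if (!any(seeds_arr))
    stop("no-thrombus-found error: no voxel in the mapped region lies in [",
         lower, ", ", upper, "] HU")
  corridor <- dilate_mask(mapped_region, max_leak_mm)
  allowed <- as.logical(corridor$mask & in_window)
  seeds0 <- which(seeds_arr) - 1L
  grown <- cpp_region_grow(g$dim, allowed, seeds0)
  final <- array(grown, dim = g$dim) & mapped_region$mask
  out <- largest_component(voxel_mask(final, g), tie_values = cta$voxels)
  if (mask_count(out) == 0L)
    stop("no-thrombus-found error: growth produced an empty mask")
  out
}
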