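# Shared fixtures, built in code at test time.

# Straight z-axis tube of enhanced lumen in parenchyma, no head/air border.
make_tube_volume <- function(dim = c(32, 32, 40), spacing = c(0.5, 0.5, 0.5),
                             radius_mm = 2, lumen_hu = 200, bg_hu = 35) {
  vox <- array(bg_hu, dim = dim)
  cx <- (dim[1] - 1) / 2 * spacing[1]
  cy <- (dim[2] - 1) / 2 * spacing[2]
  for (i in seq_len(dim[1])) for (j in seq_len(dim[2])) {
    d <- sqrt(((i - 1) * spacing[1] - cx)^2 + ((j - 1) * spacing[2] - cy)^2)
    if (d <= radius_mm) vox[i, j, ] <- lumen_hu
  }
  volume3d(vox, spacing)
}

tube_axis_seeds <- function(vol) {
  d <- dim(vol$voxels)
  rbind(c((d[1] + 1) %/% 2, (d[2] + 1) %/% 2, 2),
        c((d[1] + 1) %/% 2, (d[2] + 1) %/% 2, d[3] - 1))
}

# Reduced-size phantom spec for module-level tests (fast: ~0.3 s to render).
small_phantom_spec <- function(...) {
  args <- list(...)
  defaults <- list(
    dim = c(72, 72, 72), spacing = c(0.5, 0.5, 0.5),
    head_semiaxes = c(14, 16.5, 13),
    centerline_mm = cbind(17.75 - c(7.5, 8, 8, 7.5),
                          17.75 + c(0.5, 1.5, 0.5, -0.5),
                          c(9, 14.5, 21, 26.5)),
    vessel_radius = 2.0, thrombus_arc = c(0.3, 0.7),
    texture_scale_mm = 2.5, seed = 1L)
  do.call(phantom_spec, utils::modifyList(defaults, args))
}

random_blob_mask <- function(grid, center_frac = c(0.5, 0.5, 0.5),
                             radius_mm = 4) {
  pts <- thrombodens:::grid_points(grid)
  ctr <- grid$origin + (grid$dim - 1) * grid$spacing * center_frac
  d <- sqrt(rowSums(sweep(pts, 2, ctr, "-")^2))
  voxel_mask(array(d <= radius_mm, dim = grid$dim), grid)
}

expect_transform_close <- function(a, b, tol_deg = 1, tol_mm = 1) {
  expect_lt(max(abs(a$rotation - b$rotation)), tol_deg)
  expect_lt(max(abs(a$translation - b$translation)), tol_mm)
}
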