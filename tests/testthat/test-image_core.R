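test_that("volume and mask constructors enforce their invariants", {
  expect_error(volume3d(array(1, c(2, 2, 2)), spacing = c(0, 1, 1)),
               "spacing")
  expect_error(volume3d(array(c(1, NA), c(2, 1, 1))), "finite")
  v <- volume3d(array(50, c(4, 5, 6)), spacing = c(0.5, 0.5, 1), origin = 1:3)
  g <- thrombodens:::as_grid(v)
  expect_identical(g$dim, c(4L, 5L, 6L))
  expect_error(voxel_mask(array(TRUE, c(3, 3, 3)), g), "shape")
  m <- voxel_mask(array(rep(c(TRUE, FALSE), 60), c(4, 5, 6)), g)
  expect_equal(mask_volume_mm3(m), mask_count(m) * prod(g$spacing))
})

test_that("world/index coordinate maps are inverse and spacing-aware", {
  g <- grid3d(c(5, 6, 7), spacing = c(0.5, 2, 1.25), origin = c(-3, 4, 10))
  pts <- thrombodens:::grid_points(g)
  expect_equal(nrow(pts), prod(g$dim))
  expect_equal(pts[1, ], g$origin)
  idx <- thrombodens:::world_to_index(g, pts)
  back <- thrombodens:::index_to_world(g, idx)
  expect_equal(back, pts, tolerance = 1e-12)
  # voxel (i,j,k) sits at origin + index * spacing
  expect_equal(pts[2, ], g$origin + c(g$spacing[1], 0, 0))
})

test_that("rigid transforms compose, invert and serialize exactly", {
  tf <- rigid_transform(rotation = c(4, -3, 2), translation = c(1.5, -2, 3),
                        center = c(10, 12, 14))
  inv <- invert_transform(tf)
  pts <- matrix(runif(30, -20, 40), ncol = 3)
  round_trip <- transform_points(inv, transform_points(tf, pts))
  expect_lt(max(abs(round_trip - pts)), 1e-6)  # invertibility invariant
  f <- rigid_transform(c(1, 2, -1), c(0.5, 0, -1), c(5, 5, 5))
  comp <- compose_transforms(f, tf)
  expect_equal(transform_points(comp, pts),
               transform_points(f, transform_points(tf, pts)),
               tolerance = 1e-9)
  p <- tempfile(fileext = ".txt")
  write_transform(tf, p)
  tf2 <- read_transform(p)
  expect_equal(tf2$rotation, tf$rotation)
  expect_equal(tf2$translation, tf$translation)
  expect_equal(tf2$center, tf$center)
})

test_that("apply_transform: identity, lattice shift, inverse composition", {
  g <- grid3d(c(24, 24, 24), spacing = c(0.75, 0.75, 1.25))
  blob <- random_blob_mask(g, radius_mm = 5)
  expect_gt(mask_count(blob), 500)
  # identity on the same grid is the identity
  out <- apply_transform(blob, rigid_transform(), g)
  expect_identical(out$mask, blob$mask)
  # translation by exactly one voxel spacing shifts indices by one
  tf <- rigid_transform(translation = c(g$spacing[1], 0, 0))
  shifted <- apply_transform(blob, tf, g)
  d <- g$dim[1]
  expect_identical(shifted$mask[1:(d - 1), , ], blob$mask[2:d, , ])
  # random rigid transform then its inverse: Dice >= 0.9
  tf <- rigid_transform(rotation = c(3, -4, 5), translation = c(2, -1, 3),
                        center = thrombodens:::grid_center(g))
  fwd <- apply_transform(blob, tf, g)
  back <- apply_transform(fwd, invert_transform(tf), g)
  expect_gte(dice(back, blob), 0.9)
  # mapping the mask fully outside the grid errors
  expect_error(apply_transform(blob, rigid_transform(translation = c(500, 0, 0)), g),
               "empty-result")
})

test_that("dilation and erosion are spacing-aware and ordered", {
  g <- grid3d(c(20, 20, 20), spacing = c(0.5, 0.5, 2))
  blob <- random_blob_mask(g, radius_mm = 3)
  dil <- dilate_mask(blob, 1.0)
  ero <- erode_mask(blob, 1.0)
  expect_true(all(blob$mask[ero$mask]))
  expect_true(all(dil$mask[blob$mask]))
  expect_gt(mask_count(dil), mask_count(blob))
  expect_lt(mask_count(ero), mask_count(blob))
})
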