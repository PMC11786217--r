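test_that("volume counts occupied voxels times voxel volume", {
  one <- array(0L, c(3, 3, 3)); one[2, 2, 2] <- 1L
  expect_equal(volume_mm3(mask3d(one)), 1)
  expect_equal(volume_mm3(mask3d(array(1L, c(10, 10, 10)))), 1000)
  expect_equal(volume_mm3(mask3d(array(0L, c(4, 4, 4)))), 0)
  # spacing scales the voxel volume
  expect_equal(volume_mm3(mask3d(array(1L, c(10, 10, 10)), spacing = 0.5)),
               1000 * 0.125)
})

test_that("rendered sphere volume matches the analytic value", {
  v_true <- 4 / 3 * pi * 10^3
  expect_lt(abs(volume_mm3(sphere_mask(10, 1)) - v_true) / v_true, 0.02)
  expect_lt(abs(volume_mm3(sphere_mask(10, 0.25)) - v_true) / v_true, 0.005)
})

test_that("longest axial diameter is the in-plane Feret maximum", {
  # 11 collinear voxels along x in one slice -> 10 mm center to center
  a <- array(0L, c(15, 5, 3)); a[3:13, 3, 2] <- 1L
  expect_equal(longest_axial_diameter(mask3d(a)), 10)
  # single-voxel slice and empty mask give 0
  b <- array(0L, c(5, 5, 3)); b[3, 3, 2] <- 1L
  expect_equal(longest_axial_diameter(mask3d(b)), 0)
  expect_equal(longest_axial_diameter(mask3d(array(0L, c(4, 4, 4)))), 0)
  # sphere r=10 at 0.5 mm: within 3% of 20 mm
  expect_lt(abs(longest_axial_diameter(sphere_mask(10, 0.5)) - 20) / 20, 0.03)
  # prolate along z: the axial restriction measures the equatorial circle
  mp <- render_lesion_mask(lesion_state(semi_axes = c(5, 5, 15)), spacing = 1)
  expect_lt(abs(longest_axial_diameter(mp) - 10) / 10, 0.05)
})

test_that("size measures are translation invariant", {
  m <- render_lesion_mask(lesion_state(semi_axes = c(6, 4, 5)), spacing = 1)
  shifted <- mask3d(m$occupancy, m$spacing, m$origin + c(13.5, -7, 2))
  expect_identical(volume_mm3(m), volume_mm3(shifted))
  expect_identical(longest_axial_diameter(m), longest_axial_diameter(shifted))
})

test_that("convex-hull diameter equals the exhaustive pairwise oracle", {
  for (s in 1:25) {
    m <- random_small_mask(s)
    expect_equal(longest_axial_diameter(m), diam_oracle(m),
                 info = sprintf("seed %d", s))
  }
})

test_that("cube-root size converts volumes to a linear scale", {
  expect_equal(cube_root_size(0), 0)
  expect_equal(cube_root_size(1000), 10)
  expect_equal(cube_root_size(4188.79), 4188.79^(1 / 3), tolerance = 1e-12)
  expect_equal(cube_root_size(4188.79), 16.119, tolerance = 1e-4)
  expect_error(cube_root_size(-1), class = "ranobm_invalid_value")
})

test_that("rotation_set builds an inclusive angle grid containing 0", {
  a <- rotation_set(-20, 20, 2)
  expect_length(a, 21)
  expect_true(0 %in% a)
  expect_equal(rotation_set(0, 0, 1), 0)
  expect_length(rotation_set(-4, 4, 2), 5)
  expect_error(rotation_set(-20, 20, 0), class = "ranobm_invalid_value")
  expect_error(rotation_set(2, 20, 2), class = "ranobm_invalid_value")
  expect_error(rotation_set(-3, 3, 2), class = "ranobm_invalid_value")
})

test_that("rotation is identity at 0 and a lattice permutation at 90 degrees", {
  m <- pad_mask(render_lesion_mask(lesion_state(semi_axes = c(6, 4, 5))), 8L)
  expect_identical(rotate_mask(m, 0), m)
  for (ax in c("x", "xyz")) {
    r <- rotate_mask(m, 90, axes = ax)
    expect_identical(sum(r$occupancy), sum(m$occupancy))
  }
  # irregular mask too
  mr <- pad_mask(random_small_mask(7), 10L)
  expect_identical(sum(rotate_mask(mr, 90)$occupancy), sum(mr$occupancy))
})

test_that("rotating a sphere barely changes its measured size", {
  m <- pad_mask(sphere_mask(10, 1), 6L)
  vols <- vapply(rotation_set(-20, 20, 2),
                 function(a) volume_mm3(rotate_mask(m, a)), 0)
  expect_lt(coef_variation(cube_root_size(vols)), 0.01)
})

test_that("rotation that would clip occupied voxels is an error", {
  # long in-plane rod on a z-thin grid: tilting about x must clip
  a <- array(0L, c(9, 31, 5)); a[5, 2:30, 3] <- 1L
  expect_error(rotate_mask(mask3d(a), 20), class = "ranobm_rotation_clipped")
  expect_error(rotate_mask(mask3d(array(0L, c(4, 4, 4))), 10),
               class = "ranobm_empty_mask")
})

test_that("resampling is identity at the same spacing and preserves volume", {
  m <- sphere_mask(10, 0.5)
  expect_identical(resample_mask(m, 0.5), m)
  v_true <- 4 / 3 * pi * 1000
  r <- resample_mask(m, 1)
  expect_equal(r$spacing, c(1, 1, 1))
  expect_lt(abs(volume_mm3(r) - v_true) / v_true, 0.02)
  e <- mask3d(array(0L, c(6, 6, 6)), spacing = 0.5)
  expect_equal(volume_mm3(resample_mask(e, 1)), 0)
  expect_error(resample_mask(m, 0), class = "ranobm_invalid_value")
})
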