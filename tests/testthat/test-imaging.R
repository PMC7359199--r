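test_that("NIfTI round-trip preserves values, spacing and origin", {
  set.seed(4)
  vol <- image_volume(array(rnorm(8^3), c(8, 8, 8)),
                      spacing = c(0.98, 0.98, 3.0), origin = c(-10, 5, 2.5),
                      modality = "CT")
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path, "CT")
  expect_equal(back$values, vol$values, tolerance = 1e-6)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-6)

  msk <- roi_mask(array(rep(c(TRUE, FALSE), 256), c(8, 8, 8)), c(1, 1, 2))
  mpath <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(msk, mpath)
  expect_identical(read_mask(mpath)$values, msk$values)

  expect_error(read_volume("/nonexistent/vol.nii.gz"), "nonexistent")
})

test_that("isotropic resampling is identity at target and linear on ramps", {
  vol <- ramp_volume(8, spacing = c(3.3, 3.3, 3.3))
  expect_identical(resample_isotropic(vol, 3.3)$values, vol$values)

  # ramp 0, 2 along x at 2 mm: midpoint sample must interpolate to 1
  ramp <- image_volume(array(rep(c(0, 2), 8), c(2, 4, 2)),
                       spacing = c(2, 2, 2))
  out <- resample_isotropic(ramp, 1)
  expect_equal(out$values[2, 1, 1], 1)
  expect_equal(dim(out$values), c(3L, 7L, 3L))

  expect_error(resample_isotropic(
    image_volume(array(0, c(4, 4, 1)), c(1, 1, 5)), 2), "degenerate")
})

test_that("resampling preserves the in-mask mean of a linear field", {
  vol <- ramp_volume(32, spacing = c(1.7, 1.7, 2.9))  # intensity = 1.7 * x index
  out_v <- resample_isotropic(vol, 2.2)
  out_m <- resample_mask(roi_mask(sphere_mask(20, 1, 32)$values, vol$spacing),
                         2.2)
  # under any common mask, the interpolated mean must match the analytic
  # linear field evaluated on the same voxels
  xw <- (seq_len(dim(out_v$values)[1]) - 1) * 2.2
  analytic <- array(rep(xw, prod(dim(out_v$values)[2:3])), dim(out_v$values))
  before <- mean(analytic[out_m$values])
  after <- mean(out_v$values[out_m$values])
  expect_lt(abs(after - before) / abs(before), 0.01)
})

test_that("mask resampling keeps solid volumes and drops slivers", {
  m <- array(FALSE, c(46, 46, 46))
  m[4:43, 4:43, 4:43] <- TRUE
  cube <- roi_mask(m, c(1, 1, 1))
  out <- resample_mask(cube, 1.9)
  v_in <- sum(cube$values) * 1
  v_out <- sum(out$values) * 1.9^3
  expect_lt(abs(v_out - v_in) / v_in, 0.10)

  all1 <- roi_mask(array(TRUE, c(6, 6, 6)), c(1, 1, 1))
  expect_true(all(resample_mask(all1, 2)$values))

  lone <- array(FALSE, c(9, 9, 9)); lone[4, 5, 6] <- TRUE
  expect_error(resample_mask(roi_mask(lone, c(1, 1, 1)), 4), "vanished")
})

test_that("HU windowing is closed, idempotent and CT-restrictive", {
  vals <- array(0, c(4, 4, 4))
  vals[1, 1, 1] <- 250; vals[2, 1, 1] <- -300; vals[3, 1, 1] <- 200
  vals[4, 1, 1] <- -301
  vol <- image_volume(vals, c(1, 1, 1), modality = "CT")
  mask <- roi_mask(array(TRUE, c(4, 4, 4)), c(1, 1, 1))
  w <- apply_intensity_window(vol, mask)
  expect_false(w$values[1, 1, 1])   # 250 HU out
  expect_true(w$values[2, 1, 1])    # boundary -300 in
  expect_true(w$values[3, 1, 1])    # boundary 200 in
  expect_false(w$values[4, 1, 1])
  expect_identical(apply_intensity_window(vol, w)$values, w$values)

  mid <- image_volume(array(runif(64, -100, 100), c(4, 4, 4)), c(1, 1, 1),
                      modality = "CT")
  expect_identical(apply_intensity_window(mid, mask)$values, mask$values)

  hot <- image_volume(array(1000, c(4, 4, 4)), c(1, 1, 1), modality = "CT")
  expect_error(apply_intensity_window(hot, mask), "no tumor-range")
})

test_that("contour transfer maps CT masks onto the PET grid", {
  pet <- image_volume(array(1, c(10, 10, 10)), c(1, 1, 1), modality = "PET")
  same <- roi_mask(array(rep(c(TRUE, FALSE), 500), c(10, 10, 10)), c(1, 1, 1))
  expect_identical(transfer_mask(same, pet)$values, same$values)

  # co-registered grids whose voxel centres share the sphere centre (24.75 mm)
  ct_sphere <- sphere_mask(15, 3.3, 16)
  pet_grid <- image_volume(array(0, c(10, 10, 10)), c(5.5, 5.5, 5.5),
                           origin = rep(24.75 - 4 * 5.5, 3),
                           modality = "PET")
  out <- transfer_mask(ct_sphere, pet_grid)
  v_ct <- sum(ct_sphere$values) * 3.3^3
  v_pet <- sum(out$values) * 5.5^3
  expect_lt(abs(v_pet - v_ct) / v_ct, 0.15)

  far <- image_volume(array(0, c(5, 5, 5)), c(1, 1, 1),
                      origin = c(500, 500, 500), modality = "PET")
  expect_error(transfer_mask(ct_sphere, far), "empty")
})

test_that("fixed-bin discretization follows the floor rule and is shift-invariant", {
  arr <- array(c(0, 4.9, 5.0, 12.3), c(4, 1, 1))
  mask <- roi_mask(array(TRUE, c(4, 1, 1)), c(1, 1, 1))
  g <- discretize_fixed_bin(arr, mask, 5)
  expect_identical(as.vector(g$levels), c(1L, 1L, 2L, 3L))
  expect_identical(g$G, 3L)

  const <- discretize_fixed_bin(array(7.7, c(3, 3, 3)),
                                roi_mask(array(TRUE, c(3, 3, 3)), c(1, 1, 1)),
                                0.25)
  expect_identical(const$G, 1L)

  set.seed(9)
  vals <- array(runif(27, 0, 10), c(3, 3, 3))
  m3 <- roi_mask(array(TRUE, c(3, 3, 3)), c(1, 1, 1))
  g1 <- discretize_fixed_bin(vals, m3, 0.5)
  g2 <- discretize_fixed_bin(vals + 123.4, m3, 0.5)
  expect_identical(g1$levels, g2$levels)
})
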