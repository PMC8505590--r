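test_that("resampling honours identity, exact shifts and mask binarity", {
  case <- small_case()
  v <- case$clean_pre
  expect_identical(resample(v, rigid_transform(), v)$data, v$data)

  # whole-voxel translation: trilinear weights degenerate to 1, interior
  # voxels equal the shifted source exactly
  tf <- rigid_transform(translation = c(2, 0, 0))  # pull by +2 voxels in x
  sh <- resample(v, tf, v)
  expect_equal(sh$data[1:30, , ], v$data[3:32, , ], tolerance = 1e-12)

  mask_vol <- image_volume(array(as.numeric(case$lesion$data), dim(v$data)),
                           v$spacing)
  near <- resample(mask_vol, rigid_transform(c(3, 1, -2), c(0.4, -0.7, 0.2)),
                   v, interpolation = "nearest")
  expect_true(all(near$data %in% c(0, 1)))

  tri <- resample(v, rigid_transform(c(2, -1, 1), c(1.3, 0.2, -0.8)), v)
  tol <- 1e-9 * diff(range(v$data))
  expect_gte(min(tri$data), min(v$data) - tol)
  expect_lte(max(tri$data), max(v$data) + tol)

  expect_warning(resample(v, rigid_transform(translation = c(500, 0, 0)), v),
                 "no overlap")
})

test_that("bias correction leaves constant volumes alone and recovers known fields", {
  const <- image_volume(array(50, c(24, 24, 24)))
  out <- correct_bias(const, roi_mask(array(TRUE, c(24, 24, 24)), const),
                      bias_params(grid_mm = 12))
  expect_lt(max(abs(out$field$data - 1)), 0.01)
  expect_equal(out$corrected$data, const$data, tolerance = 0.01)

  # noiseless phantom under a strong smooth field: correction restores the
  # clean anatomy almost perfectly
  spec <- small_spec(bias_amplitude = 0.3, noise_sd = 0)
  case <- generate_phantom(spec)
  bc <- correct_bias(case$pre1, NULL, bias_params(grid_mm = 16))
  br <- case$brain$data
  expect_gt(cor(bc$corrected$data[br], case$clean_pre$data[br]), 0.99)
  expect_true(all(bc$field$data > 0))

  # the ROI-mean intensity moves by no more than the field normalisation (1%)
  mask <- otsu_mask(case$pre1)
  expect_lt(abs(mean(bc$corrected$data[mask$data]) /
                  mean(case$pre1$data[mask$data]) - 1), 0.01)
})

test_that("bias correction rejects non-positive intensities in the mask", {
  v <- image_volume(array(c(-1, rep(10, 13823)), c(24, 24, 24)))
  expect_error(correct_bias(v, roi_mask(array(TRUE, c(24, 24, 24)), v)),
               "non-positive")
})

test_that("registration recovers identity and known rigid perturbations", {
  case <- small_case()
  v <- case$clean_pre
  idt <- register_rigid(v, v, light_reg())
  expect_lt(max(abs(idt$translation)), 0.1)
  expect_lt(max(abs(idt$rotation)), 0.1)

  tf_t <- rigid_transform(translation = c(3, -2, 1.5))
  moved <- degrade_exam(v, transform = tf_t)
  rec <- register_rigid(moved, v, light_reg())
  expect_lt(max(abs(rec$translation - (-tf_t$translation))), 0.5)

  # rotation recovery needs a lever arm: at very small fields of view the
  # metric's own maximum sits a fraction of a degree off, so test at 48^3
  big <- cached("reg48", generate_phantom(
    phantom_spec(shape = c(48, 48, 48), lesion_centre_mm = c(30, 27, 24),
                 lesion_radius_mm = 8, core_radius_mm = 4)))
  vb <- big$clean_pre
  ctr <- (dim(vb$data) - 1) * vb$spacing / 2
  tf_r <- rigid_transform(rotation = c(0, 0, 3), centre = ctr)
  rot <- degrade_exam(vb, transform = tf_r)
  rec_r <- register_rigid(rot, vb,
                          registration_params(levels = 2, max_iters = 120,
                                              sampling = 0.5))
  truth <- qea:::invert_transform(tf_r)
  expect_lt(max(abs(rec_r$rotation - truth$rotation)), 0.5)
  expect_lt(max(abs(rec_r$translation - truth$translation)), 0.5)
})

test_that("mutual information peaks at alignment", {
  case <- small_case()
  v <- case$clean_pre
  ctr <- (dim(v$data) - 1) * v$spacing / 2
  mi0 <- mutual_information(v, v, rigid_transform(centre = ctr))
  set.seed(3)
  for (i in 1:20) {
    tf <- rigid_transform(runif(3, -4, 4), runif(3, -4, 4), centre = ctr)
    expect_gte(mi0, mutual_information(v, v, tf))
  }
})
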