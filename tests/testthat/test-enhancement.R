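test_that("noise sigma estimation is robust, scale-equivariant and guarded", {
  v <- image_volume(array(7, c(10, 10, 10)))
  bg <- roi_mask(array(TRUE, c(10, 10, 10)), v)
  expect_equal(estimate_noise_sigma(v, bg), 0)

  case <- generate_phantom(small_spec(noise_sd = 5))
  bgm <- roi_mask(!case$brain$data, case$pre1)
  sig <- estimate_noise_sigma(case$pre1, bgm)
  expect_lt(abs(sig - 5) / 5, 0.1)

  doubled <- image_volume(2 * case$pre1$data, case$pre1$spacing)
  expect_equal(estimate_noise_sigma(doubled, bgm), 2 * sig, tolerance = 1e-12)

  tiny <- roi_mask(array(c(rep(TRUE, 50), rep(FALSE, 950)), c(10, 10, 10)), v)
  expect_error(estimate_noise_sigma(v, tiny), ">= 100")
})

test_that("threshold derivation follows its definitions and error paths", {
  vals <- array(0.1 * seq_len(1000), c(10, 10, 10))
  sub <- image_volume(vals)
  brain <- roi_mask(array(TRUE, c(10, 10, 10)), sub)
  fz <- derive_thresholds(sub, brain, sigma = 5, k = 2, p_sat = 99)
  expect_equal(fz$theta_low, 10)
  expect_lt(abs(fz$theta_high - 99.0), 0.1)

  neg <- image_volume(array(-abs(vals), c(10, 10, 10)))
  expect_error(derive_thresholds(neg, brain, sigma = 5), "no enhancement signal")
})

test_that("fuzzification maps enhancement to memberships on the ramp", {
  d <- c(8, 8, 8)
  pre <- image_volume(array(100, d))
  fz <- fuzz_params(10, 50)

  expect_true(all(compute_qem(pre, pre, fz)$data == 0))  # bright but unchanged

  post <- image_volume(array(100 + 60, d))               # above theta_high
  expect_true(all(compute_qem(pre, post, fz)$data == 1))

  mid <- image_volume(array(100 + 30, d))                # ramp midpoint
  expect_true(all(compute_qem(pre, mid, fz)$data == 0.5))

  # darker than white matter yet brighter post than pre still scores > 0
  dark_pre <- image_volume(array(40, d))
  dark_post <- image_volume(array(40 + 25, d))
  expect_true(all(compute_qem(dark_pre, dark_post, fz)$data > 0))

  # negative enhancement clips to zero, not negative membership
  less <- image_volume(array(80, d))
  expect_true(all(compute_qem(pre, less, fz)$data == 0))
})

test_that("QEM bounds and monotonicity hold for arbitrary inputs", {
  set.seed(9)
  d <- c(10, 10, 10)
  for (i in 1:5) {
    pre <- image_volume(array(runif(1000, -50, 150), d))
    post <- image_volume(array(runif(1000, -50, 250), d))
    fz <- fuzz_params(runif(1, 0, 5), runif(1, 6, 60))
    q <- compute_qem(pre, post, fz)
    expect_true(all(q$data >= 0 & q$data <= 1))
    bump <- compute_qem(pre, image_volume(post$data + 10, post$spacing), fz)
    expect_true(all(bump$data >= q$data))
  }
})

test_that("change maps subtract, antisymmetrise and guard their inputs", {
  case <- small_case()
  d <- dim(case$clean_pre$data)
  q1 <- qem_of(array(runif(prod(d)), d))
  q2 <- qem_of(array(runif(prod(d)), d))
  expect_true(all(change_map(q1, q1)$data == 0))
  expect_equal(change_map(q1, q2)$data, -change_map(q2, q1)$data)
  expect_true(all(change_map(q1, q2)$data >= -1 & change_map(q1, q2)$data <= 1))

  roi <- case$lesion
  inroi <- array(0, d); inroi[roi$data] <- 1
  cm <- change_map(qem_of(inroi), qem_of(array(0, d)))
  expect_true(all(cm$data[roi$data] == 1))

  mism <- compute_qem(image_volume(array(0, d)), image_volume(inroi, c(1, 1, 1)),
                      fuzz_params(0, 2))
  expect_error(change_map(q1, mism), "different thresholds")
})

test_that("scatter data pairs ROI voxels faithfully", {
  d <- c(6, 6, 6)
  set.seed(21)
  pre <- image_volume(array(runif(216, 0, 100), d))
  post <- image_volume(array(runif(216, 0, 100), d))
  m <- array(FALSE, d); m[sample(216, 7)] <- TRUE
  ref <- image_volume(array(0, d))
  roi <- roi_mask(m, ref)
  sc <- scatter_data(pre, post, roi)
  expect_equal(nrow(sc), 7)
  idx <- which(roi$data)
  expect_equal(sc$pre, pre$data[idx])
  expect_equal(sc$post, post$data[idx])

  sc_id <- scatter_data(pre, pre, roi)
  expect_true(all(sc_id$pre == sc_id$post))

  expect_error(scatter_data(pre, post, roi_mask(array(FALSE, d), ref)), "empty")
})
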