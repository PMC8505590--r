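test_that("intensity mappings validate, interpolate and extrapolate linearly", {
  expect_error(intensity_mapping(c(0, 1, 1), c(0, 1, 2)), "strictly increasing")
  expect_error(intensity_mapping(c(0, 1, 2), c(0, 2, 1)), "strictly increasing")
  m <- intensity_mapping(c(0, 10), c(0, 20))
  expect_equal(evaluate_mapping(m, 5), 10)
  expect_equal(evaluate_mapping(m, -5), -10)   # linear extrapolation below
  expect_equal(evaluate_mapping(m, 15), 30)    # and above

  v <- image_volume(array(runif(8^3, 0, 100), c(8, 8, 8)))
  ident <- intensity_mapping(c(0, 100), c(0, 100))
  expect_equal(apply_mapping(v, ident)$data, v$data)
})

test_that("mappings preserve rank order of voxels", {
  set.seed(11)
  v <- image_volume(array(runif(10^3, 0, 50), c(10, 10, 10)))
  x <- sort(runif(6, 0, 50)); x <- x + seq_along(x) * 1e-6
  y <- cumsum(runif(6, 0.1, 5))
  m <- intensity_mapping(x, y)
  out <- apply_mapping(v, m)
  expect_identical(order(v$data), order(out$data))
})

test_that("quantile oracle recovers identity and linear distortions", {
  case <- small_case()
  ref <- case$pre1   # noisy: a continuous intensity distribution
  m_id <- quantile_match_oracle(ref, ref)
  probe <- seq(quantile(ref$data, 0.01), quantile(ref$data, 0.99), length.out = 50)
  rng <- diff(range(ref$data))
  expect_lt(max(abs(evaluate_mapping(m_id, probe) - probe)), 0.01 * rng)

  doubled <- image_volume(2 * ref$data, ref$spacing)
  m2 <- quantile_match_oracle(doubled, ref)
  mapped <- evaluate_mapping(m2, 2 * probe)
  expect_lt(max(abs(mapped - probe)), 0.02 * rng)
})

test_that("GA fit is deterministic, monotone, and never below the oracle", {
  case <- small_case()
  ref <- case$pre1
  target <- image_volume(1.4 * ref$data + 10, ref$spacing)

  f1 <- fit_harmonisation(target, ref, params = light_ga(7L))
  f2 <- fit_harmonisation(target, ref, params = light_ga(7L))
  expect_identical(f1$x, f2$x); expect_identical(f1$y, f2$y)

  mapped <- apply_mapping(target, f1)
  rng <- diff(range(ref$data))
  sup <- ref$data > quantile(ref$data, 0.01) & ref$data < quantile(ref$data, 0.99)
  expect_lt(max(abs(mapped$data[sup] - ref$data[sup])), 0.02 * rng)

  for (s in 1:10) {
    fs <- fit_harmonisation(target, ref,
                            params = ga_params(population = 12,
                                               generations = 10, seed = s))
    expect_true(all(diff(fs$x) > 0) && all(diff(fs$y) > 0))
    expect_gte(attr(fs, "fitness"), attr(fs, "oracle_fitness") - 1e-12)
  }
})

test_that("GA matches the oracle across phantom scale/offset configurations", {
  set.seed(5)
  for (i in 1:5) {
    case <- cached(paste0("harm", i),
                   generate_phantom(small_spec(seed = 100L + i)))
    s <- runif(1, 0.7, 1.5); o <- runif(1, -10, 20)
    target <- image_volume(s * case$pre1$data + o, case$pre1$spacing)
    fit <- fit_harmonisation(target, case$pre1, exclude = case$lesion,
                             params = light_ga(i))
    expect_gte(attr(fit, "fitness"), attr(fit, "oracle_fitness") - 0.05)
  }
})

test_that("fitting on non-lesion support does not suppress true enhancement", {
  spec <- phantom_spec(shape = c(32, 32, 32), lesion_centre_mm = c(20, 18, 16),
                       lesion_radius_mm = 6, core_radius_mm = 3,
                       bias_amplitude = 0,
                       perturb_rotation_deg = c(0, 0, 0),
                       perturb_translation_mm = c(0, 0, 0))
  case <- generate_phantom(spec)
  fit <- fit_harmonisation(case$post1, case$pre1, exclude = case$lesion,
                           params = light_ga(3L))
  post_h <- apply_mapping(case$post1, fit)
  # analytic inversion of the known scale/offset
  post_true <- image_volume((case$post1$data - spec$intensity_offset) /
                              spec$intensity_scale, case$pre1$spacing)
  brain <- case$brain
  sigma <- estimate_noise_sigma(case$pre1, roi_mask(!brain$data, case$pre1))
  sub_true <- image_volume(post_true$data - case$pre1$data, case$pre1$spacing)
  fuzz <- derive_thresholds(sub_true, brain, sigma)
  q_ga <- compute_qem(case$pre1, post_h, fuzz)
  q_true <- compute_qem(case$pre1, post_true, fuzz)
  les <- case$lesion$data
  expect_gte(mean(q_ga$data[les]), 0.9 * mean(q_true$data[les]))
})

test_that("tiny fit supports are rejected", {
  v <- image_volume(array(runif(1000), c(10, 10, 10)))
  excl <- roi_mask(array(c(rep(FALSE, 500), rep(TRUE, 500)), c(10, 10, 10)), v)
  expect_error(fit_harmonisation(v, v, exclude = excl), "support")
})
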