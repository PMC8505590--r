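test_that("ROI summaries follow their arithmetic definitions", {
  d <- c(10, 10, 10)
  ref <- image_volume(array(0, d))
  m <- array(FALSE, d); m[1:100] <- TRUE
  roi <- roi_mask(m, ref)

  z <- summarise_roi(qem_of(array(0, d)), roi)
  expect_equal(z$net_qe, 0); expect_equal(z$avg_qe, 0)

  u <- array(0, d); u[1:100] <- 0.5
  s <- summarise_roi(qem_of(u), roi)
  expect_equal(s$net_qe, 50)
  expect_equal(s$avg_qe, 0.5)
  expect_equal(s$volume_cm3, 0.1)
  expect_equal(s$n_voxels, 100)
  expect_equal(s$weighted_volume, 0.05)
})

test_that("net QE is additive over disjoint ROI splits", {
  case <- small_case()
  d <- dim(case$membership$data)
  q <- qem_of(case$membership$data)
  les <- case$lesion$data
  idx <- which(les)
  half <- array(FALSE, d); half[idx[seq(1, length(idx), 2)]] <- TRUE
  other <- les & !half
  ref <- image_volume(array(0, d))
  s_all <- summarise_roi(q, roi_mask(les, ref))
  s_a <- summarise_roi(q, roi_mask(half, ref))
  s_b <- summarise_roi(q, roi_mask(other, ref))
  expect_equal(s_a$net_qe + s_b$net_qe, s_all$net_qe)
  expect_equal(s_a$n_voxels + s_b$n_voxels, s_all$n_voxels)
})

test_that("max extent equals the brute-force pairwise maximum", {
  d <- c(16, 16, 16)
  ref_iso <- image_volume(array(0, d))
  one <- array(FALSE, d); one[5, 5, 5] <- TRUE
  expect_equal(max_extent(roi_mask(one, ref_iso)), 0)

  two <- array(FALSE, d); two[3, 5, 5] <- TRUE; two[6, 5, 5] <- TRUE
  expect_equal(max_extent(roi_mask(two, ref_iso)), 3.0)

  set.seed(13)
  for (i in 1:5) {
    sp <- if (i %% 2 == 0) c(1, 1, 4) else c(1, 1, 1)
    ref <- image_volume(array(0, d), spacing = sp)
    m <- array(FALSE, d)
    seedpt <- sample(3:14, 3)
    n_target <- sample(30:200, 1)
    # random connected-ish blob around a seed point
    pts <- unique(rbind(seedpt,
                        t(replicate(n_target,
                                    pmin(pmax(seedpt + sample(-4:4, 3, TRUE),
                                              1), 16)))))
    m[pts] <- TRUE
    roi <- roi_mask(m, ref)
    coords <- sweep(which(m, arr.ind = TRUE) - 1, 2, sp, "*")
    brute <- max(as.matrix(dist(coords)))
    expect_equal(max_extent(roi), brute, tolerance = 1e-12)
  }
})

test_that("equivalence verdicts follow the 90% CI against the zone", {
  d <- c(10, 10, 10)
  ref <- image_volume(array(0, d))
  roi <- roi_mask(array(TRUE, d), ref)
  q <- qem_of(array(runif(1000, 0.2, 0.8), d))
  eq <- equivalence_test(q, q, roi)
  expect_equal(eq$mean_diff, 0)
  expect_equal(eq$ci90, c(0, 0))
  expect_true(eq$equivalent)

  # a genuine 0.3 shift: the CI lands tightly around it, outside the zone
  set.seed(31)
  base <- array(runif(1000, 0.3, 0.6), d)
  shift <- array(pmin(pmax(rnorm(1000, 0.3, 0.05), 0), 1), d)
  q1 <- qem_of(base + 0); q2 <- qem_of(base)
  q1$data <- pmin(base + shift, 1)  # keep memberships in [0, 1]
  eq2 <- equivalence_test(qem_of(q1$data), q2, roi)
  expect_gt(eq2$ci90[1], 0.28)
  expect_lt(eq2$ci90[2], 0.32)
  expect_false(eq2$equivalent)
  expect_lt(eq2$ci90[2] - eq2$ci90[1],
            2 * qt(0.95, 999) * 0.06 / sqrt(1000) * 1.5)

  # the study's worked case: a 0.0025 mean difference is equivalent
  small <- array(rnorm(1000, 0.0025, 0.01), d)
  q3 <- qem_of(pmin(pmax(0.5 + small, 0), 1))
  q4 <- qem_of(array(0.5, d))
  eq3 <- equivalence_test(q3, q4, roi)
  expect_true(abs(eq3$mean_diff - 0.0025) < 0.002)
  expect_true(eq3$equivalent)

  expect_error(equivalence_test(q, q, roi_mask(array(FALSE, d), ref)),
               "at least 2|empty")
})

test_that("the enhancement-presence exclusion rule is inclusive at its threshold", {
  d <- c(8, 8, 8)
  ref <- image_volume(array(0, d))
  roi <- roi_mask(array(TRUE, d), ref)
  expect_false(enhancement_present(qem_of(array(0, d)), roi))
  expect_true(enhancement_present(qem_of(array(0.1, d)), roi, min_avg = 0.01))
  expect_true(enhancement_present(qem_of(array(0.01, d)), roi, min_avg = 0.01))
  expect_false(enhancement_present(qem_of(array(0.00999, d)), roi,
                                   min_avg = 0.01))
})

test_that("amplitude asymmetry drives the equivalence verdict with the right sign", {
  # truth-harmonised QEMs isolate the ROI-level property from fit noise
  mk_qems <- function(amp) {
    spec <- small_spec(amp = amp, bias_amplitude = 0,
                       perturb_rotation_deg = c(0, 0, 0),
                       perturb_translation_mm = c(0, 0, 0), seed = 303L)
    case <- generate_phantom(spec)
    s <- spec$intensity_scale; o <- spec$intensity_offset
    un <- function(v) image_volume((v$data - o) / s, v$spacing)
    brain <- case$brain
    sigma <- estimate_noise_sigma(case$pre1, roi_mask(!brain$data, case$pre1))
    sub1 <- image_volume(un(case$post1)$data - case$pre1$data, spec$spacing)
    fz <- derive_thresholds(sub1, brain, sigma)
    list(q1 = compute_qem(case$pre1, un(case$post1), fz),
         q2 = compute_qem(un(case$pre2), un(case$post2), fz),
         roi = case$lesion)
  }
  eq <- mk_qems(c(0.7, 0.7))
  res_eq <- equivalence_test(eq$q1, eq$q2, eq$roi)
  expect_true(res_eq$equivalent)

  # agent 2 at 1.5x the amplitude saturates the rim that agent 1 only ramps:
  # its QEM is larger, so mean_diff (agent 1 - agent 2) is negative
  asym <- mk_qems(c(0.6, 0.9))
  res_as <- equivalence_test(asym$q1, asym$q2, asym$roi)
  expect_lt(res_as$mean_diff, -0.02)
})
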