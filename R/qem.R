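#' Fuzzification parameters for the enhancement membership scale
#'
#' The voxelwise enhancement value `e = post - pre` (harmonised intensities)
#' is mapped to membership by a clipped linear ramp: 0 at or below
#' `theta_low`, 1 at or above `theta_high`, linear in between.
#'
#' @param theta_low enhancement value below which membership is 0
#'   (intensity units, `>= 0`); calibrated as `k` times the noise SD.
#' @param theta_high value at/above which membership is 1
#'   (`> theta_low`); calibrated as the `p_sat`-th percentile of positive
#'   enhancement.
#' @param k,p_sat the calibration constants used (recorded for provenance).
#' @return An object of class `fuzz_params`.
#' @export
fuzz_params <- function(theta_low, theta_high, k = NA_real_, p_sat = NA_real_) {
  stopifnot(is.finite(theta_low), is.finite(theta_high))
  if (theta_low < 0) stop("theta_low must be >= 0")
  if (theta_high <= theta_low) stop("theta_high must exceed theta_low")
  structure(list(theta_low = theta_low, theta_high = theta_high,
                 k = k, p_sat = p_sat),
            class = "fuzz_params")
}

#' Estimate the image noise SD from a background region
#'
#' Robust scale estimate: 1.4826 times the median absolute deviation of the
#' background intensities, consistent with a Gaussian SD.
#'
#' @param pre an [image_volume] (typically the unenhanced reference image).
#' @param background an [roi_mask] of at least 100 signal-free voxels.
#' @return Estimated noise SD (intensity units, `>= 0`).
#' @export
estimate_noise_sigma <- function(pre, background) {
  stopifnot(inherits(pre, "image_volume"), inherits(background, "roi_mask"))
  check_same_grid(pre, background, "volume and background mask")
  v <- pre$data[background$data]
  if (length(v) < 100L)
    stop("background mask has ", length(v), " voxels; need >= 100")
  stats::mad(v, constant = 1.4826)
}

#' Derive fuzzification thresholds from the first examination
#'
#' `theta_low = k * sigma` (a noise floor) and `theta_high` is the
#' `p_sat`-th percentile of the positive subtraction values within the
#' brain. Thresholds are derived once per patient from examination 1 and
#' reused unchanged for examination 2, so that calibration cannot absorb a
#' genuine between-agent difference. If `theta_high` fails to clear
#' `theta_low` by at least one noise SD the exam carries no enhancement
#' signal (pure noise places the 99th percentile of positive values near
#' 2.6 sigma) and an error is raised; the pipeline converts this condition
#' into the patient-level no-enhancement exclusion.
#'
#' @param subtraction an [image_volume] of `post - pre` (harmonised).
#' @param brain an [roi_mask] restricting the calibration.
#' @param sigma noise SD from [estimate_noise_sigma()].
#' @param k noise-floor multiplier (default 2).
#' @param p_sat saturation percentile (default 99, a robust maximum).
#' @return A [fuzz_params].
#' @export
derive_thresholds <- function(subtraction, brain, sigma, k = 2, p_sat = 99) {
  stopifnot(inherits(subtraction, "image_volume"), inherits(brain, "roi_mask"),
            sigma >= 0, k >= 0, p_sat > 0, p_sat <= 100)
  check_same_grid(subtraction, brain, "subtraction and brain mask")
  pos <- subtraction$data[brain$data]
  pos <- pos[pos > 0]
  if (length(pos) == 0L)
    stop("no enhancement signal: no positive subtraction values within the brain")
  theta_low <- k * sigma
  theta_high <- as.numeric(stats::quantile(pos, p_sat / 100, names = FALSE))
  # the saturation point must at least double the noise floor (and clear it
  # by one noise SD): pure noise puts the 99th percentile of positive values
  # near 2.6 sigma, and residual harmonisation/registration artifacts reach
  # 3-4 sigma, so a ramp that stays inside that range would grade noise and
  # preprocessing residue rather than enhancement
  if (theta_high <= theta_low + max(sigma, theta_low))
    stop("no enhancement signal: the ", p_sat,
         "th percentile of positive enhancement (", signif(theta_high, 4),
         ") does not clear the noise floor (theta_low ",
         signif(theta_low, 4), ", sigma ", signif(sigma, 4), ")")
  fuzz_params(theta_low, theta_high, k = k, p_sat = p_sat)
}

#' Compute a quantitative enhancement map (QEM)
#'
#' Subtracts the harmonised unenhanced image from the contrast-enhanced one
#' and fuzzifies the result: membership
#' `clip((e - theta_low) / (theta_high - theta_low), 0, 1)`. Voxels equally
#' bright before and after contrast map to 0 however bright they are, and
#' voxels darker than white matter still score above 0 whenever they are
#' brighter post than pre — the map grades enhancement, not brightness.
#' Negative enhancement maps to 0: the membership scale is `[0, 1]`.
#'
#' @param pre_h,post_h harmonised [image_volume] pair on the common grid.
#' @param fuzz a [fuzz_params].
#' @param agent optional agent label stored in provenance.
#' @return An object of class `qe_map`: an [image_volume]-like structure
#'   with a `provenance` field carrying the agent and thresholds.
#' @export
compute_qem <- function(pre_h, post_h, fuzz, agent = NA_character_) {
  stopifnot(inherits(pre_h, "image_volume"), inherits(post_h, "image_volume"),
            inherits(fuzz, "fuzz_params"))
  check_same_grid(pre_h, post_h, "pre and post volumes")
  e <- post_h$data - pre_h$data
  m <- pmin(pmax((e - fuzz$theta_low) / (fuzz$theta_high - fuzz$theta_low),
                 0), 1)
  structure(list(data = array(m, dim = dim(pre_h$data)),
                 spacing = pre_h$spacing, origin = pre_h$origin,
                 provenance = list(agent = agent,
                                   theta_low = fuzz$theta_low,
                                   theta_high = fuzz$theta_high)),
            class = c("qe_map", "image_volume"))
}

#' @export
print.qe_map <- function(x, ...) {
  cat("<qe_map> ", paste(dim(x$data), collapse = " x "), " voxels, agent ",
      x$provenance$agent, ", thresholds (",
      signif(x$provenance$theta_low, 4), ", ",
      signif(x$provenance$theta_high, 4), ")\n", sep = "")
  invisible(x)
}

#' QE change map between two agents
#'
#' Voxelwise difference `q1 - q2` of two QEMs on the same grid, in
#' `[-1, 1]`; positive where agent 1 enhances more. The two maps must carry
#' identical fuzzification thresholds — per-agent calibration would let the
#' calibration absorb the very difference being measured.
#'
#' @param q1,q2 [compute_qem()] outputs on the same grid.
#' @return An object of class `change_map` (an [image_volume]-like
#'   structure).
#' @export
change_map <- function(q1, q2) {
  stopifnot(inherits(q1, "qe_map"), inherits(q2, "qe_map"))
  check_same_grid(q1, q2, "QE maps")
  check_shared_thresholds(q1, q2)
  structure(list(data = q1$data - q2$data, spacing = q1$spacing,
                 origin = q1$origin,
                 provenance = list(agents = c(q1$provenance$agent,
                                              q2$provenance$agent))),
            class = c("change_map", "image_volume"))
}

check_shared_thresholds <- function(q1, q2) {
  if (!isTRUE(all.equal(c(q1$provenance$theta_low, q1$provenance$theta_high),
                        c(q2$provenance$theta_low, q2$provenance$theta_high))))
    stop("QE maps were fuzzified with different thresholds (",
         signif(q1$provenance$theta_low, 4), ", ",
         signif(q1$provenance$theta_high, 4), ") vs (",
         signif(q2$provenance$theta_low, 4), ", ",
         signif(q2$provenance$theta_high, 4),
         "); both agents must share one calibration")
  invisible(TRUE)
}

#' Scatter data of contrast-enhanced versus unenhanced intensities
#'
#' One `(pre, post)` pair per ROI voxel in the array's native (column-major)
#' voxel order. After harmonisation, nonenhancing voxels cluster along the
#' identity line and enhancing voxels deviate above it.
#'
#' @param pre_h,post_h harmonised [image_volume] pair.
#' @param roi a non-empty [roi_mask].
#' @return A data frame with columns `pre` and `post`.
#' @export
scatter_data <- function(pre_h, post_h, roi) {
  stopifnot(inherits(roi, "roi_mask"))
  check_same_grid(pre_h, post_h, "pre and post volumes")
  check_same_grid(pre_h, roi, "volume and ROI")
  idx <- which(roi$data)
  if (length(idx) == 0L) stop("ROI is empty")
  data.frame(pre = pre_h$data[idx], post = post_h$data[idx])
}
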