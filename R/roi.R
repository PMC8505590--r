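#' Per-ROI enhancement summary
#'
#' Net QE is the sum of QEM memberships over the ROI: a joint expression of
#' how much tissue enhances and how strongly. The per-ROI average QE (net
#' QE divided by the voxel count) is its size-normalised companion in
#' `[0, 1]`. `weighted_volume` expresses the same sum in enhancement-cm^3.
#'
#' @param qem a [compute_qem()] output (or any [image_volume] of
#'   memberships).
#' @param roi a non-empty [roi_mask] on the same grid.
#' @return An object of class `roi_summary` with fields `net_qe`,
#'   `n_voxels`, `volume_cm3`, `max_extent_mm`, `avg_qe`,
#'   `weighted_volume`.
#' @export
summarise_roi <- function(qem, roi) {
  stopifnot(inherits(qem, "image_volume"), inherits(roi, "roi_mask"))
  check_same_grid(qem, roi, "QE map and ROI")
  idx <- which(roi$data)
  if (length(idx) == 0L) stop("ROI is empty")
  vox_mm3 <- prod(roi$spacing)
  net <- sum(qem$data[idx])
  structure(list(net_qe = net,
                 n_voxels = length(idx),
                 volume_cm3 = length(idx) * vox_mm3 / 1000,
                 max_extent_mm = max_extent(roi),
                 avg_qe = net / length(idx),
                 weighted_volume = net * vox_mm3 / 1000),
            class = "roi_summary")
}

#' @export
print.roi_summary <- function(x, ...) {
  cat("<roi_summary> net QE ", round(x$net_qe, 1), " over ", x$n_voxels,
      " voxels (avg ", round(x$avg_qe, 3), "), volume ",
      round(x$volume_cm3, 3), " cm^3, max extent ",
      round(x$max_extent_mm, 1), " mm\n", sep = "")
  invisible(x)
}

#' Maximum spatial extent of an ROI
#'
#' The largest Euclidean distance between any two ROI voxel centres in
#' physical units (the 3-D maximum calliper). Computed over the mask's
#' surface voxels only — the farthest pair always lies on the surface — in
#' memory-bounded chunks.
#'
#' @param roi a non-empty [roi_mask].
#' @return Distance in mm (0 for a single voxel).
#' @export
max_extent <- function(roi) {
  stopifnot(inherits(roi, "roi_mask"))
  idx <- which(roi$data)
  if (length(idx) == 0L) stop("ROI is empty")
  if (length(idx) == 1L) return(0)
  d <- dim(roi$data)
  sub <- arrayInd(idx, d)
  # surface voxels: any 6-neighbour outside the mask (or at the array edge)
  m <- roi$data
  interior <- rep(TRUE, nrow(sub))
  for (ax in 1:3) {
    for (dir in c(-1L, 1L)) {
      nb <- sub
      nb[, ax] <- nb[, ax] + dir
      on_grid <- nb[, ax] >= 1L & nb[, ax] <= d[ax]
      inside <- rep(FALSE, nrow(sub))
      inside[on_grid] <- m[nb[on_grid, , drop = FALSE]]
      interior <- interior & inside
    }
  }
  sub <- sub[!interior, , drop = FALSE]
  pts <- sweep(sub - 1, 2, roi$spacing, "*")
  n <- nrow(pts)
  sq <- rowSums(pts^2)
  best <- 0
  chunk <- max(1L, 2000000L %/% n)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    d2 <- outer(sq[rows], sq, "+") - 2 * pts[rows, , drop = FALSE] %*% t(pts)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

#' Voxelwise equivalence test between two QEMs over an ROI
#'
#' Tests whether two agents' enhancement is statistically equivalent: the
#' mean voxelwise QEM difference over the ROI and its two-sided 90%
#' t confidence interval are computed, and the agents are declared
#' equivalent when the interval lies entirely within the equivalence zone
#' `(-zone, +zone)`. ROI voxels are treated as independent; spatial
#' autocorrelation is ignored (a documented caveat of the voxelwise test).
#'
#' @param q1,q2 [compute_qem()] outputs on the same grid, sharing one
#'   threshold calibration.
#' @param roi an [roi_mask] with at least 2 voxels.
#' @param zone half-width of the equivalence zone (default 0.2).
#' @param level confidence level (default 0.90).
#' @return An object of class `equivalence_result` with fields `mean_diff`,
#'   `sd_diff`, `n`, `ci90` (length-2), `zone`, `equivalent`.
#' @export
equivalence_test <- function(q1, q2, roi, zone = 0.2, level = 0.90) {
  stopifnot(inherits(roi, "roi_mask"), zone > 0, level > 0, level < 1)
  check_same_grid(q1, q2, "QE maps")
  check_same_grid(q1, roi, "QE map and ROI")
  if (inherits(q1, "qe_map") && inherits(q2, "qe_map"))
    check_shared_thresholds(q1, q2)
  dv <- (q1$data - q2$data)[roi$data]
  n <- length(dv)
  if (n < 2L) stop("equivalence test needs at least 2 ROI voxels, got ", n)
  mean_diff <- mean(dv)
  sd_diff <- stats::sd(dv)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * sd_diff / sqrt(n)
  ci <- c(mean_diff - half, mean_diff + half)
  structure(list(mean_diff = mean_diff, sd_diff = sd_diff, n = n,
                 ci90 = ci, zone = c(-zone, zone),
                 equivalent = ci[1] > -zone && ci[2] < zone),
            class = "equivalence_result")
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat("<equivalence_result> mean diff ", signif(x$mean_diff, 4), ", ",
      "90% CI [", signif(x$ci90[1], 4), ", ", signif(x$ci90[2], 4),
      "], zone (", x$zone[1], ", ", x$zone[2], ") -> ",
      if (x$equivalent) "equivalent" else "not equivalent", "\n", sep = "")
  invisible(x)
}

#' Does an ROI show any enhancement?
#'
#' The cohort exclusion rule: patients whose lesion shows no signal
#' enhancement on the generated QEM on either examination are excluded from
#' analysis. An exam counts as enhancing when the per-ROI average QE is at
#' least `min_avg` (inclusive).
#'
#' @param qem a [compute_qem()] output.
#' @param roi a non-empty [roi_mask].
#' @param min_avg minimum per-ROI average QE (default 0.01).
#' @return `TRUE` if the ROI's average membership reaches `min_avg`.
#' @export
enhancement_present <- function(qem, roi, min_avg = 0.01) {
  stopifnot(inherits(qem, "image_volume"), inherits(roi, "roi_mask"))
  check_same_grid(qem, roi, "QE map and ROI")
  idx <- which(roi$data)
  if (length(idx) == 0L) stop("ROI is empty")
  mean(qem$data[idx]) >= min_avg
}
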