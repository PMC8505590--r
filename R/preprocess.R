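#' Bias-field correction parameters
#'
#' @param grid_mm control-grid resolution of the smooth field model, mm.
#'   The number of cosine modes per axis is the grid extent divided by this.
#' @param iters maximum fit iterations (split across resolution levels).
#' @param levels number of coarse-to-fine levels (mode counts grow per level).
#' @param tol convergence tolerance on the log-field update.
#' @return An object of class `bias_params`.
#' @export
bias_params <- function(grid_mm = 32, iters = 12, levels = 2, tol = 1e-4) {
  stopifnot(grid_mm > 0, iters > 0, levels >= 1, tol > 0)
  structure(list(grid_mm = grid_mm, iters = iters, levels = levels, tol = tol),
            class = "bias_params")
}

#' Rigid registration parameters
#'
#' @param bins number of intensity histogram bins for mutual information
#'   (`>= 8`).
#' @param levels multi-resolution levels (downsampling by `2^(levels-1)`
#'   down to full resolution).
#' @param max_iters Nelder-Mead iterations per level.
#' @param sampling fraction of fixed-image voxels sampled for the metric,
#'   in `(0, 1]` (taken as a deterministic stride).
#' @param tol relative convergence tolerance of the optimiser.
#' @return An object of class `registration_params`.
#' @export
registration_params <- function(bins = 32, levels = 3, max_iters = 200,
                                sampling = 0.25, tol = 1e-8) {
  stopifnot(bins >= 8, levels >= 1, max_iters >= 1,
            sampling > 0, sampling <= 1, tol > 0)
  structure(list(bins = as.integer(bins), levels = as.integer(levels),
                 max_iters = as.integer(max_iters), sampling = sampling,
                 tol = tol),
            class = "registration_params")
}

#' Resample a volume through a rigid transform onto a reference grid
#'
#' Pull-style resampling: the output voxel at world point `p` takes the
#' source volume's (interpolated) value at `transform(p)`. Points falling
#' outside the source grid become background 0. Trilinear interpolation is
#' used for intensities; nearest-neighbour preserves binary masks.
#'
#' @param vol source [image_volume].
#' @param transform a [rigid_transform] mapping reference-space points into
#'   `vol`'s space.
#' @param reference an [image_volume] or [roi_mask] defining the output grid.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return An [image_volume] on the reference grid.
#' @export
resample <- function(vol, transform = rigid_transform(), reference = vol,
                     interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(vol, "image_volume"))
  same_grid <- identical(dim(vol$data), dim(reference$data)) &&
    max(abs(vol$spacing - reference$spacing)) < 1e-9 &&
    max(abs(vol$origin - reference$origin)) < 1e-9
  if (is_identity_transform(transform) && same_grid)
    return(image_volume(vol$data, vol$spacing, vol$origin))
  pts <- grid_world_coords(reference)
  src <- apply_transform(transform, pts)
  ci <- sweep(sweep(src, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
  d <- dim(vol$data)
  out <- numeric(nrow(ci))
  if (interpolation == "nearest") {
    ri <- round(ci)
    ok <- ri[, 1] >= 1 & ri[, 1] <= d[1] & ri[, 2] >= 1 & ri[, 2] <= d[2] &
      ri[, 3] >= 1 & ri[, 3] <= d[3]
    idx <- ri[ok, 1] + (ri[ok, 2] - 1) * d[1] + (ri[ok, 3] - 1) * d[1] * d[2]
    out[ok] <- vol$data[idx]
  } else {
    eps <- 1e-7
    ok <- ci[, 1] >= 1 - eps & ci[, 1] <= d[1] + eps &
      ci[, 2] >= 1 - eps & ci[, 2] <= d[2] + eps &
      ci[, 3] >= 1 - eps & ci[, 3] <= d[3] + eps
    c1 <- pmin(pmax(ci[ok, 1], 1), d[1])
    c2 <- pmin(pmax(ci[ok, 2], 1), d[2])
    c3 <- pmin(pmax(ci[ok, 3], 1), d[3])
    i0 <- pmin(floor(c1), d[1] - 1); f1 <- c1 - i0
    j0 <- pmin(floor(c2), d[2] - 1); f2 <- c2 - j0
    k0 <- pmin(floor(c3), d[3] - 1); f3 <- c3 - k0
    base <- i0 + (j0 - 1) * d[1] + (k0 - 1) * d[1] * d[2]
    sx <- 1; sy <- d[1]; sz <- d[1] * d[2]
    v <- vol$data
    out[ok] <-
      v[base]                * (1 - f1) * (1 - f2) * (1 - f3) +
      v[base + sx]           * f1       * (1 - f2) * (1 - f3) +
      v[base + sy]           * (1 - f1) * f2       * (1 - f3) +
      v[base + sx + sy]      * f1       * f2       * (1 - f3) +
      v[base + sz]           * (1 - f1) * (1 - f2) * f3 +
      v[base + sx + sz]      * f1       * (1 - f2) * f3 +
      v[base + sy + sz]      * (1 - f1) * f2       * f3 +
      v[base + sx + sy + sz] * f1       * f2       * f3
  }
  if (!any(ok))
    warning("resampled volume has no overlap with the source; output is all background")
  image_volume(array(out, dim = dim(reference$data)),
               spacing = reference$spacing, origin = reference$origin)
}

# block-mean downsampling by integer factor (spacing scales accordingly)
downsample_volume <- function(vol, factor) {
  if (factor == 1L) return(vol)
  d <- dim(vol$data)
  nd <- d %/% factor
  a <- vol$data[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                seq_len(nd[3] * factor), drop = FALSE]
  dim(a) <- c(factor, nd[1], factor * nd[2] * factor * nd[3])
  a <- colMeans(a); dim(a) <- c(nd[1], factor, nd[2], factor * nd[3])
  a <- aperm(a, c(2, 1, 3, 4))
  dim(a) <- c(factor, nd[1] * nd[2], factor * nd[3])
  a <- colMeans(a); dim(a) <- c(nd[1], nd[2], factor, nd[3])
  a <- aperm(a, c(3, 1, 2, 4))
  dim(a) <- c(factor, nd[1] * nd[2] * nd[3])
  a <- colMeans(a); dim(a) <- nd
  image_volume(a, spacing = vol$spacing * factor,
               origin = vol$origin + (factor - 1) / 2 * vol$spacing)
}

# Shannon mutual information (nats) between paired intensity samples,
# on a bins x bins joint histogram over precomputed ranges
mi_from_samples <- function(fx, mv, bins, f_range, m_range) {
  fb <- pmin(pmax(floor((fx - f_range[1]) / (f_range[2] - f_range[1]) * bins) + 1,
                  1), bins)
  mb <- pmin(pmax(floor((mv - m_range[1]) / (m_range[2] - m_range[1]) * bins) + 1,
                  1), bins)
  joint <- tabulate(fb + (mb - 1L) * bins, nbins = bins * bins)
  p <- joint / sum(joint)
  pf <- rowSums(matrix(p, bins, bins))
  pm <- colSums(matrix(p, bins, bins))
  nz <- p > 0
  outer_pm <- as.vector(outer(pf, pm))
  sum(p[nz] * log(p[nz] / outer_pm[nz]))
}

# trilinear interpolation of a volume at arbitrary world points (NA outside)
interp_at <- function(vol, pts) {
  d <- dim(vol$data)
  ci1 <- (pts[, 1] - vol$origin[1]) / vol$spacing[1] + 1
  ci2 <- (pts[, 2] - vol$origin[2]) / vol$spacing[2] + 1
  ci3 <- (pts[, 3] - vol$origin[3]) / vol$spacing[3] + 1
  ok <- ci1 >= 1 & ci1 <= d[1] & ci2 >= 1 & ci2 <= d[2] &
    ci3 >= 1 & ci3 <= d[3]
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  i0 <- pmin(floor(ci1[ok]), d[1] - 1); f1 <- ci1[ok] - i0
  j0 <- pmin(floor(ci2[ok]), d[2] - 1); f2 <- ci2[ok] - j0
  k0 <- pmin(floor(ci3[ok]), d[3] - 1); f3 <- ci3[ok] - k0
  sy <- d[1]; sz <- d[1] * d[2]
  base <- i0 + (j0 - 1) * sy + (k0 - 1) * sz
  v <- vol$data
  out[ok] <- v[base] * (1 - f1) * (1 - f2) * (1 - f3) +
    v[base + 1] * f1 * (1 - f2) * (1 - f3) +
    v[base + sy] * (1 - f1) * f2 * (1 - f3) +
    v[base + 1 + sy] * f1 * f2 * (1 - f3) +
    v[base + sz] * (1 - f1) * (1 - f2) * f3 +
    v[base + 1 + sz] * f1 * (1 - f2) * f3 +
    v[base + sy + sz] * (1 - f1) * f2 * f3 +
    v[base + 1 + sy + sz] * f1 * f2 * f3
  out
}

# builds a fast metric evaluator with the sample points, fixed intensities
# and histogram ranges precomputed once. Sample points are jittered by a
# deterministic sub-voxel offset: sampling exactly at voxel centres creates
# a spurious metric maximum wherever a transform aligns the sample lattice
# with the moving grid (no interpolation blur there), and off-grid sampling
# removes that artifact
make_mi_evaluator <- function(moving, fixed, bins, stride) {
  pts <- grid_world_coords(fixed)
  if (stride > 1L) {
    keep <- seq(1L, nrow(pts), by = stride)
    pts <- pts[keep, , drop = FALSE]
  }
  jit <- withr::with_seed(20210412L,
    matrix(stats::runif(length(pts), -0.45, 0.45), ncol = 3))
  pts <- pts + sweep(jit, 2, fixed$spacing, "*")
  fx_all <- interp_at(fixed, pts)
  fin <- !is.na(fx_all)
  pts <- pts[fin, , drop = FALSE]
  fx <- fx_all[fin]
  f_range <- range(fx); m_range <- range(moving$data)
  degenerate <- length(fx) < 2L ||
    diff(f_range) == 0 || diff(m_range) == 0
  function(transform) {
    if (degenerate) return(0)
    A <- transform_affine(transform)
    src <- sweep(pts %*% t(A[1:3, 1:3]), 2, A[1:3, 4], "+")
    mv <- interp_at(moving, src)
    ok <- !is.na(mv)
    if (sum(ok) < 2L) return(-Inf)
    mi <- mi_from_samples(fx[ok], mv[ok], bins, f_range, m_range)
    overlap <- mean(ok)
    if (overlap < 0.5) mi <- mi * overlap / 0.5
    mi
  }
}

#' Mutual information between a fixed volume and a transformed moving volume
#'
#' Evaluates the registration metric at an arbitrary transform: the moving
#' volume is trilinearly sampled at the transformed fixed-grid points and
#' the Shannon mutual information (in nats) of the joint intensity histogram
#' is returned. Samples that leave the moving volume are discarded; if fewer
#' than half remain, the score is penalised in proportion to the lost
#' overlap so the optimiser cannot profit from shrinking it.
#'
#' @param moving,fixed [image_volume] objects.
#' @param transform a [rigid_transform] (pull convention).
#' @param bins histogram bins.
#' @param stride deterministic voxel subsampling stride (1 = all voxels).
#' @return Mutual information in nats.
#' @export
mutual_information <- function(moving, fixed, transform = rigid_transform(),
                               bins = 32, stride = 1L) {
  make_mi_evaluator(moving, fixed, bins, stride)(transform)
}

#' Rigid registration by maximisation of mutual information
#'
#' Estimates the 6-parameter rigid transform aligning `moving` to `fixed`
#' with a multi-resolution Nelder-Mead search over the mutual-information
#' metric. The returned transform is in the pull convention: passing it to
#' [resample()] with `reference = fixed` produces the aligned moving image.
#' If the optimum scores below the identity transform at full resolution,
#' the identity is returned instead (the metric postcondition).
#'
#' @param moving,fixed [image_volume] objects with overlapping extent.
#' @param params a [registration_params].
#' @param init optional initial [rigid_transform].
#' @return A [rigid_transform] with attributes `mi` (final metric value)
#'   and `trace` (per-level optimiser summaries).
#' @export
register_rigid <- function(moving, fixed, params = registration_params(),
                           init = NULL) {
  stopifnot(inherits(moving, "image_volume"), inherits(fixed, "image_volume"))
  centre <- fixed$origin + (dim(fixed$data) - 1) * fixed$spacing / 2
  par <- if (is.null(init)) rep(0, 6) else
    c(init$rotation, init$translation)
  factors <- rev(2^(seq_len(params$levels) - 1))
  stride <- max(1L, as.integer(round(1 / params$sampling)))
  trace <- list()
  sweep_done <- FALSE
  for (f in factors) {
    mv <- downsample_volume(moving, f)
    fx <- downsample_volume(fixed, f)
    evaluator <- make_mi_evaluator(mv, fx, params$bins,
                                   if (f == 1L) stride else 1L)
    fn <- function(p) {
      mi <- evaluator(rigid_transform(p[1:3], p[4:6], centre))
      if (!is.finite(mi) && !identical(mi, -Inf))
        stop("registration metric became non-finite at parameters (",
             paste(signif(p, 4), collapse = ", "), ")")
      -mi
    }
    # grids too coarse to resolve the anatomy determine rotation poorly (a
    # near-symmetric brain rotated several degrees can score better than the
    # truth there, stranding the finer levels outside their capture range):
    # such levels refine translation only
    if (min(dim(fx$data)) < 20L) {
      rot_fixed <- par[1:3]
      fn_t <- function(pt) fn(c(rot_fixed, pt))
      opt <- stats::optim(par[4:6], fn_t, method = "Nelder-Mead",
                          control = list(maxit = params$max_iters,
                                         reltol = params$tol,
                                         parscale = rep(max(1, f), 3)))
      par[4:6] <- opt$par
      trace[[length(trace) + 1L]] <- list(factor = f, restart = 0L,
                                          mi = -opt$value,
                                          evals = opt$counts[["function"]])
      next
    }
    # once, at the coarsest level that still resolves the anatomy (very
    # coarse grids make large rotations of near-symmetric brains spuriously
    # competitive), sweep each parameter over a +/-3 deg/mm grid: the
    # histogram metric has micro-plateaus that stall a small simplex long
    # before it has travelled the few degrees/millimetres of real motion
    if (!sweep_done && min(dim(fx$data)) >= 20L) {
      grid <- seq(-3, 3, by = 1)
      base_val <- fn(par)
      for (ax in 1:6) {
        cand <- vapply(grid, function(g) {
          p <- par; p[ax] <- p[ax] + g; fn(p)
        }, numeric(1))
        if (min(cand) < base_val - 1e-3) {
          par[ax] <- par[ax] + grid[which.min(cand)]
          base_val <- min(cand)
        }
      }
      sweep_done <- TRUE
    }
    # restart the simplex until the metric stops improving: Nelder-Mead
    # collapses early on plateaus, and a fresh simplex around the current
    # optimum recovers the remaining fraction of a degree/millimetre
    restarts <- if (f == 1L) 4L else 2L
    value <- Inf
    for (r in seq_len(restarts)) {
      opt <- stats::optim(par, fn, method = "Nelder-Mead",
                          control = list(maxit = params$max_iters,
                                         reltol = params$tol,
                                         parscale = rep(max(1, f) / r, 6)))
      improved <- value - opt$value
      par <- opt$par
      value <- opt$value
      trace[[length(trace) + 1L]] <- list(factor = f, restart = r,
                                          mi = -opt$value,
                                          evals = opt$counts[["function"]])
      if (r > 1L && improved < 1e-5) break
    }
  }
  best <- rigid_transform(par[1:3], par[4:6], centre)
  evaluator <- make_mi_evaluator(moving, fixed, params$bins, stride)
  mi_best <- evaluator(best)
  candidates <- list(rigid_transform(centre = centre))
  if (!is.null(init))
    candidates <- c(candidates,
                    list(rigid_transform(init$rotation, init$translation,
                                         centre)))
  for (cand in candidates) {
    mi_cand <- evaluator(cand)
    if (mi_cand > mi_best) {
      best <- cand
      mi_best <- mi_cand
    }
  }
  attr(best, "mi") <- mi_best
  attr(best, "trace") <- trace
  best
}

# global Otsu threshold on a 256-bin histogram (maximises between-class
# variance); used to derive a foreground/brain mask when none is supplied
otsu_threshold <- function(x, nbins = 256L) {
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(floor((x - r[1]) / diff(r) * nbins) + 1L, nbins),
                nbins = nbins)
  w <- h / sum(h)
  omega <- cumsum(w)
  mu <- cumsum(w * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  r[1] + k / nbins * diff(r)
}

#' Foreground (brain) mask by global Otsu thresholding
#' @param vol an [image_volume].
#' @return An [roi_mask] of voxels above the Otsu threshold.
#' @export
otsu_mask <- function(vol) {
  thr <- otsu_threshold(as.vector(vol$data))
  roi_mask(vol$data > thr, vol)
}

# tensor-product cosine basis evaluated at normalised coordinates;
# coords: n x 3 in [0,1], modes: m x 3 integer orders
cosine_basis <- function(coords, modes) {
  B <- matrix(1, nrow(coords), nrow(modes))
  for (m in seq_len(nrow(modes)))
    B[, m] <- cos(pi * modes[m, 1] * coords[, 1]) *
      cos(pi * modes[m, 2] * coords[, 2]) *
      cos(pi * modes[m, 3] * coords[, 3])
  B
}

# deterministic 1-D k-means (Lloyd from quantile-initialised centres)
kmeans_1d <- function(x, k = 3L, iters = 12L) {
  centres <- as.numeric(stats::quantile(x, probs = seq(0.15, 0.85,
                                                       length.out = k)))
  assign <- rep(1L, length(x))
  for (it in seq_len(iters)) {
    dmat <- abs(outer(x, centres, "-"))
    assign <- max.col(-dmat, ties.method = "first")
    for (j in seq_len(k)) {
      xs <- x[assign == j]
      if (length(xs)) centres[j] <- mean(xs)
    }
  }
  list(assign = assign, centres = centres)
}

#' Multiplicative bias-field correction
#'
#' Log-domain smooth-field estimation: the log image within the mask is
#' modelled as a piecewise-constant tissue term (three intensity classes,
#' re-estimated each iteration) plus a smooth field spanned by low-order
#' 3-D cosine modes, fitted coarse-to-fine by least squares. The recovered
#' field is exponentiated, normalised to mean 1 over the mask, and divided
#' out. Intensities must be strictly positive within the mask.
#'
#' @param vol an [image_volume].
#' @param mask optional [roi_mask] of voxels to fit (default: Otsu
#'   foreground of `vol`).
#' @param params a [bias_params].
#' @return List with `corrected` (an [image_volume]) and `field`
#'   (the strictly positive multiplicative field, an [image_volume]).
#' @export
correct_bias <- function(vol, mask = NULL, params = bias_params()) {
  stopifnot(inherits(vol, "image_volume"))
  if (is.null(mask)) mask <- otsu_mask(vol)
  check_same_grid(vol, mask, "volume and mask")
  inside <- which(mask$data)
  if (length(inside) < 100L) stop("mask too small for bias estimation")
  if (any(vol$data[inside] <= 0))
    stop("non-positive intensities inside the mask; remove any negative ",
         "offset before log-domain bias correction")
  d <- dim(vol$data)
  extent <- (d - 1) * vol$spacing
  n_modes <- max(1L, min(4L, as.integer(round(mean(extent) / params$grid_mm))))
  # subsample masked voxels for the fit
  stride <- max(1L, length(inside) %/% 40000L)
  fit_idx <- inside[seq(1L, length(inside), by = stride)]
  kk <- arrayInd(fit_idx, d)
  coords <- sweep(kk - 1, 2, d - 1, "/")
  u <- log(vol$data[fit_idx])
  mode_orders <- as.matrix(expand.grid(0:n_modes, 0:n_modes, 0:n_modes))
  mode_orders <- mode_orders[rowSums(mode_orders) > 0 &
                               rowSums(mode_orders) <= n_modes, , drop = FALSE]
  level_caps <- unique(pmin(seq_len(params$levels) *
                              ceiling(n_modes / params$levels), n_modes))
  iters_per <- max(2L, params$iters %/% length(level_caps))
  field_log <- numeric(length(fit_idx))
  coef <- NULL; use <- NULL
  for (cap in level_caps) {
    use <- rowSums(mode_orders) <= cap
    B <- cosine_basis(coords, mode_orders[use, , drop = FALSE])
    for (it in seq_len(iters_per)) {
      km <- kmeans_1d(u - field_log, k = 3L)
      resid <- u - km$centres[km$assign]
      coef <- stats::lm.fit(B, resid)$coefficients
      coef[is.na(coef)] <- 0
      # trimmed refit: voxels far from any tissue class (lesion rim,
      # partial volume) would otherwise drag the smooth field
      r2 <- abs(resid - as.numeric(B %*% coef))
      keep_fit <- r2 <= stats::quantile(r2, 0.9)
      coef <- stats::lm.fit(B[keep_fit, , drop = FALSE],
                            resid[keep_fit])$coefficients
      coef[is.na(coef)] <- 0
      new_field <- as.numeric(B %*% coef)
      new_field <- new_field - mean(new_field)
      delta <- max(abs(new_field - field_log))
      field_log <- new_field
      if (delta < params$tol) break
    }
  }
  # evaluate the fitted modes over the whole grid
  xt <- (seq_len(d[1]) - 1) / (d[1] - 1)
  yt <- (seq_len(d[2]) - 1) / (d[2] - 1)
  zt <- (seq_len(d[3]) - 1) / (d[3] - 1)
  full <- array(0, dim = d)
  mo <- mode_orders[use, , drop = FALSE]
  for (m in seq_len(nrow(mo)))
    full <- full + coef[m] * outer(outer(cos(pi * mo[m, 1] * xt),
                                         cos(pi * mo[m, 2] * yt)),
                                   cos(pi * mo[m, 3] * zt))
  field <- exp(full)
  field <- field / mean(field[inside])
  corrected <- vol$data / field
  list(corrected = image_volume(corrected, vol$spacing, vol$origin),
       field = image_volume(field, vol$spacing, vol$origin))
}
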