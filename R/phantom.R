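#' Specification of a two-agent digital brain phantom
#'
#' Describes a paired crossover acquisition: one brain-like object imaged
#' four times (unenhanced + contrast-enhanced, once per agent) with a
#' spherical lesion whose enhancing rim carries a known fuzzy membership
#' map. The degradations emulate the physics the pipeline must undo:
#' a smooth multiplicative bias field per acquisition, a small rigid
#' misalignment of the second examination, a global intensity scale/offset
#' difference between acquisitions, and additive Gaussian noise.
#'
#' Default values describe a plausible 1.5-T T1 spin-echo brain study:
#' tissue intensities in the conventional CSF < GM < WM ordering, a strongly
#' rim-enhancing lesion (80% of white-matter intensity added at full
#' membership, i.e. rim SNR 32 against the default noise), a 20% bias-field
#' range, millimetre-scale inter-exam motion and a 15%/8-unit scanner
#' gain/offset drift.
#'
#' @param shape integer length-3 grid size in voxels.
#' @param spacing numeric length-3 voxel size, mm.
#' @param tissues named list/vector with `csf`, `gm`, `wm` intensities.
#' @param lesion_centre_mm lesion centre in world mm.
#' @param lesion_radius_mm outer lesion radius, mm.
#' @param core_radius_mm non-enhancing necrotic core radius, mm
#'   (must be `< lesion_radius_mm`).
#' @param amp length-2 per-agent enhancement amplitudes `c(a1, a2)`:
#'   fraction of WM intensity added where membership is 1.
#' @param bias_amplitude multiplicative bias range `beta`, `0 <= beta < 1`.
#' @param perturb_rotation_deg,perturb_translation_mm rigid perturbation of
#'   examination 2 relative to examination 1.
#' @param intensity_scale,intensity_offset global scale `s` and offset `o`
#'   applied to every acquisition after the reference one.
#' @param noise_sd additive Gaussian noise SD, intensity units.
#' @param seed integer RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64),
                         spacing = c(1, 1, 1),
                         tissues = list(csf = 30, gm = 70, wm = 100),
                         lesion_centre_mm = c(42, 38, 32),
                         lesion_radius_mm = 10,
                         core_radius_mm = 5,
                         amp = c(0.8, 0.8),
                         bias_amplitude = 0.2,
                         perturb_rotation_deg = c(1.5, -1.0, 0.8),
                         perturb_translation_mm = c(2.0, -1.5, 1.0),
                         intensity_scale = 1.15,
                         intensity_offset = 8,
                         noise_sd = 2.5,
                         seed = 1L) {
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               tissues = as.list(tissues),
               lesion_centre_mm = as.numeric(lesion_centre_mm),
               lesion_radius_mm = lesion_radius_mm,
               core_radius_mm = core_radius_mm,
               amp = as.numeric(amp),
               bias_amplitude = bias_amplitude,
               perturb_rotation_deg = as.numeric(perturb_rotation_deg),
               perturb_translation_mm = as.numeric(perturb_translation_mm),
               intensity_scale = intensity_scale,
               intensity_offset = intensity_offset,
               noise_sd = noise_sd,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  stopifnot(length(s$shape) == 3L, all(s$shape >= 8L),
            length(s$spacing) == 3L, all(s$spacing > 0),
            all(c("csf", "gm", "wm") %in% names(s$tissues)))
  if (s$core_radius_mm >= s$lesion_radius_mm)
    stop("core radius must be smaller than the outer lesion radius")
  if (any(s$amp < 0)) stop("enhancement amplitudes must be >= 0")
  if (s$noise_sd < 0) stop("noise SD must be >= 0")
  if (s$bias_amplitude < 0 || s$bias_amplitude >= 1)
    stop("bias amplitude must lie in [0, 1)")
  extent <- (s$shape - 1) * s$spacing
  lo <- s$lesion_centre_mm - s$lesion_radius_mm
  hi <- s$lesion_centre_mm + s$lesion_radius_mm
  if (any(lo < 0) || any(hi > extent))
    stop("lesion (centre ", paste(s$lesion_centre_mm, collapse = ", "),
         " mm, radius ", s$lesion_radius_mm, " mm) extends outside the grid")
  invisible(s)
}

# radial distance (mm) of every voxel centre from the lesion centre
lesion_radii <- function(spec) {
  d <- spec$shape
  dx <- (seq_len(d[1]) - 1) * spec$spacing[1] - spec$lesion_centre_mm[1]
  dy <- (seq_len(d[2]) - 1) * spec$spacing[2] - spec$lesion_centre_mm[2]
  dz <- (seq_len(d[3]) - 1) * spec$spacing[3] - spec$lesion_centre_mm[3]
  r2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
  sqrt(r2)
}

#' True enhancement membership map of a phantom
#'
#' Membership is 1 on the rim mid-surface (radius midway between the core
#' and outer radii), tapers linearly to 0 at both the core boundary and the
#' outer lesion boundary, and is exactly 0 inside the core and outside the
#' lesion. This is the quantity the pipeline's QEM estimates.
#'
#' @param spec a [phantom_spec].
#' @return An [image_volume] of memberships in `[0, 1]`.
#' @export
make_membership <- function(spec) {
  validate_phantom_spec(spec)
  r <- lesion_radii(spec)
  rc <- spec$core_radius_mm
  ro <- spec$lesion_radius_mm
  rm <- (rc + ro) / 2
  m <- array(0, dim = spec$shape)
  up <- r > rc & r <= rm
  dn <- r > rm & r < ro
  m[up] <- (r[up] - rc) / (rm - rc)
  m[dn] <- (ro - r[dn]) / (ro - rm)
  image_volume(m, spacing = spec$spacing)
}

# clean (undegraded) unenhanced brain: ellipsoidal brain with a GM shell,
# WM interior, a CSF ventricle, and the lesion core darkened to CSF-like
# intensity so the "visibly abnormal" region includes the core
make_clean_brain <- function(spec) {
  d <- spec$shape
  extent <- (d - 1) * spec$spacing
  ctr <- extent / 2
  x <- (seq_len(d[1]) - 1) * spec$spacing[1]
  y <- (seq_len(d[2]) - 1) * spec$spacing[2]
  z <- (seq_len(d[3]) - 1) * spec$spacing[3]
  semi <- 0.45 * extent
  u2 <- outer(outer(((x - ctr[1]) / semi[1])^2,
                    ((y - ctr[2]) / semi[2])^2, "+"),
              ((z - ctr[3]) / semi[3])^2, "+")
  brain <- u2 <= 1
  gm_shell <- u2 <= 1 & u2 > 0.72          # outer ~15% of the radius
  vent_semi <- pmax(0.12 * extent, 3)
  v2 <- outer(outer(((x - ctr[1]) / vent_semi[1])^2,
                    ((y - ctr[2]) / vent_semi[2])^2, "+"),
              ((z - ctr[3]) / vent_semi[3])^2, "+")
  vent <- v2 <= 1
  arr <- array(0, dim = d)
  arr[brain] <- spec$tissues$wm
  arr[gm_shell] <- spec$tissues$gm
  arr[vent] <- spec$tissues$csf
  r <- lesion_radii(spec)
  arr[r <= spec$core_radius_mm & brain] <- spec$tissues$csf
  list(volume = image_volume(arr, spacing = spec$spacing),
       brain = brain)
}

# smooth multiplicative bias field: 1 + beta * f(x) with f a seeded random
# combination of low-order 3-D cosine modes normalised to [-1, 1]
make_bias_field <- function(shape, spacing, beta, seed) {
  d <- shape
  if (beta == 0) return(array(1, dim = d))
  xt <- (seq_len(d[1]) - 1) / (d[1] - 1)
  yt <- (seq_len(d[2]) - 1) / (d[2] - 1)
  zt <- (seq_len(d[3]) - 1) / (d[3] - 1)
  modes <- expand.grid(kx = 0:2, ky = 0:2, kz = 0:2)
  modes <- modes[rowSums(modes) >= 1 & rowSums(modes) <= 2, ]
  coef <- withr::with_seed(seed, stats::rnorm(nrow(modes)))
  f <- array(0, dim = d)
  for (i in seq_len(nrow(modes))) {
    f <- f + coef[i] * outer(outer(cos(pi * modes$kx[i] * xt),
                                   cos(pi * modes$ky[i] * yt)),
                             cos(pi * modes$kz[i] * zt))
  }
  f <- f / max(abs(f))
  1 + beta * f
}

#' Degrade one acquisition
#'
#' Applies, in acquisition order: rigid resampling (patient repositioning),
#' multiplicative bias (coil shading), global scale/offset (scanner gain),
#' then additive Gaussian noise. With the identity transform and all other
#' degradations at zero, the output equals the input exactly.
#'
#' @param vol clean [image_volume].
#' @param bias_amplitude bias range `beta` in `[0, 1)`.
#' @param transform [rigid_transform] pulling output points into `vol`
#'   (identity = no motion).
#' @param scale,offset global intensity scale and offset.
#' @param noise_sd additive Gaussian noise SD (`>= 0`).
#' @param seed integer seed for the bias field and noise.
#' @return A degraded [image_volume] on the same grid.
#' @export
degrade_exam <- function(vol, bias_amplitude = 0, transform = rigid_transform(),
                         scale = 1, offset = 0, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(vol, "image_volume"), noise_sd >= 0)
  out <- if (is_identity_transform(transform)) vol$data else
    resample(vol, transform, vol, interpolation = "trilinear")$data
  if (bias_amplitude > 0)
    out <- out * make_bias_field(dim(vol$data), vol$spacing,
                                 bias_amplitude, seed)
  out <- out * scale + offset
  if (noise_sd > 0)
    out <- out + withr::with_seed(seed + 1L,
      array(stats::rnorm(length(out), sd = noise_sd), dim = dim(out)))
  image_volume(out, spacing = vol$spacing, origin = vol$origin)
}

#' Generate a complete two-agent phantom case
#'
#' Produces the four acquisitions (`pre1`, `post1`, `pre2`, `post2`) plus
#' every ground truth a downstream test needs: the membership map, the
#' lesion ROI, the per-image bias fields, the exam-2 rigid perturbation
#' (in the pull convention used by [resample()]) and the per-image
#' scale/offset. The clean (undegraded) volumes are retained under
#' `clean_pre` / `clean_post` for oracle comparisons.
#'
#' Enhancement model: `post_clean = pre_clean + a_k * m(x) * I_WM`, so the
#' maximally enhancing voxel gains a known additive amount and membership
#' recovery is checkable. Examination 1 defines the reference frame and
#' intensity scale; `post1`, `pre2` and `post2` receive the global
#' scale/offset of `spec`, and the exam-2 pair is rigidly perturbed.
#'
#' @param spec a [phantom_spec].
#' @param seed integer seed; defaults to `spec$seed`. Identical spec + seed
#'   gives bit-identical volumes.
#' @return An object of class `phantom_case`.
#' @export
generate_phantom <- function(spec, seed = spec$seed) {
  validate_phantom_spec(spec)
  seed <- as.integer(seed)
  clean <- make_clean_brain(spec)
  m <- make_membership(spec)
  wm <- spec$tissues$wm
  post_clean <- lapply(1:2, function(k)
    image_volume(clean$volume$data + spec$amp[k] * m$data * wm,
                 spacing = spec$spacing))
  perturb <- rigid_transform(spec$perturb_rotation_deg,
                             spec$perturb_translation_mm,
                             centre = (spec$shape - 1) * spec$spacing / 2)
  s <- spec$intensity_scale; o <- spec$intensity_offset
  idt <- rigid_transform()
  pre1  <- degrade_exam(clean$volume,  spec$bias_amplitude, idt, 1, 0,
                        spec$noise_sd, seed * 10L + 1L)
  post1 <- degrade_exam(post_clean[[1]], spec$bias_amplitude, idt, s, o,
                        spec$noise_sd, seed * 10L + 3L)
  pre2  <- degrade_exam(clean$volume,  spec$bias_amplitude, perturb, s, o,
                        spec$noise_sd, seed * 10L + 5L)
  post2 <- degrade_exam(post_clean[[2]], spec$bias_amplitude, perturb, s, o,
                        spec$noise_sd, seed * 10L + 7L)
  r <- lesion_radii(spec)
  lesion <- roi_mask(r <= spec$lesion_radius_mm, clean$volume)
  structure(list(
    spec = spec, seed = seed,
    pre1 = pre1, post1 = post1, pre2 = pre2, post2 = post2,
    clean_pre = clean$volume, clean_post = post_clean,
    membership = m, lesion = lesion,
    brain = roi_mask(clean$brain, clean$volume),
    bias_fields = lapply(c(1L, 3L, 5L, 7L), function(off)
      make_bias_field(spec$shape, spec$spacing, spec$bias_amplitude,
                      seed * 10L + off)),
    perturbation = perturb,
    scale_offset = list(pre1 = c(1, 0), post1 = c(s, o),
                        pre2 = c(s, o), post2 = c(s, o))),
    class = "phantom_case")
}

#' Write a phantom case to disk
#'
#' Writes the four acquisitions, truth membership and lesion mask as NIfTI
#' plus a JSON truth record (perturbation, scale/offset, spec echo).
#'
#' @param case a `phantom_case` from [generate_phantom()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_phantom <- function(case, dir) {
  stopifnot(inherits(case, "phantom_case"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(pre1 = "pre1.nii.gz", post1 = "post1.nii.gz",
             pre2 = "pre2.nii.gz", post2 = "post2.nii.gz",
             membership = "truth_membership.nii.gz",
             lesion = "truth_lesion_mask.nii.gz")
  for (nm in names(paths))
    write_volume(case[[nm]], file.path(dir, paths[[nm]]))
  truth <- list(seed = case$seed,
                perturbation = case$perturbation[c("rotation", "translation",
                                                   "centre")],
                scale_offset = case$scale_offset,
                spec = unclass(case$spec))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, c(paths, "truth.json")))
}
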