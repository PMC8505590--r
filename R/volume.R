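#' 3-D image volume with physical geometry
#'
#' The basic unit every pipeline stage consumes and produces: a 3-D scalar
#' array together with its voxel spacing (mm) and physical origin (mm).
#' Voxel centres define positions; the world coordinate of voxel
#' `(i, j, k)` (1-based R indexing) is `origin + (c(i, j, k) - 1) * spacing`,
#' following the NIfTI RAS+ convention for axis-aligned volumes.
#' Intensities are held as 64-bit doubles regardless of on-disk type, since
#' the pipeline mixes subtraction and optimisation and integer truncation
#' would corrupt enhancement maps.
#'
#' @param data numeric 3-D array; must be finite everywhere.
#' @param spacing numeric length-3, per-axis voxel size in mm, all `> 0`.
#' @param origin numeric length-3, world coordinate of the first voxel centre.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array, got ", length(dim(data)), " dimension(s)")
  if (any(dim(data) < 1L))
    stop("all three dimensions must be positive")
  n_bad <- sum(!is.finite(data))
  if (n_bad > 0L)
    stop("volume contains ", n_bad, " non-finite voxel(s); clean the input first")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive voxel sizes in mm")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be three finite world coordinates in mm")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n  intensity range [", signif(min(x$data), 5), ", ",
      signif(max(x$data), 5), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Binary region-of-interest mask tied to a reference grid
#'
#' @param data logical (or coercible) 3-D array.
#' @param reference an [image_volume] whose geometry the mask shares.
#' @return An object of class `roi_mask` carrying the reference geometry.
#' @export
roi_mask <- function(data, reference) {
  stopifnot(inherits(reference, "image_volume"))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask 'data' must be a 3-D array")
  if (!identical(dim(data), dim(reference$data)))
    stop("mask shape (", paste(dim(data), collapse = "x"),
         ") does not match reference shape (",
         paste(dim(reference$data), collapse = "x"), ")")
  m <- array(as.logical(data != 0 & !is.na(data)), dim = dim(data))
  structure(list(data = m, spacing = reference$spacing,
                 origin = reference$origin),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> ", paste(dim(x$data), collapse = " x "), " voxels, ",
      sum(x$data), " in mask\n", sep = "")
  invisible(x)
}

# shared geometry check used by every stage that pairs grids
check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data), dim(b$data)))
    stop(what, " have different shapes: ",
         paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"))
  if (max(abs(a$spacing - b$spacing)) > 1e-4)
    stop(what, " have different spacings: (",
         paste(signif(a$spacing, 6), collapse = ", "), ") vs (",
         paste(signif(b$spacing, 6), collapse = ", "), ") mm")
  invisible(TRUE)
}

nifti_affine <- function(spacing, origin) {
  rbind(cbind(diag(spacing), origin), c(0, 0, 0, 1))
}

#' Read a 3-D NIfTI-1 volume
#'
#' Loads a `.nii`/`.nii.gz` file into an [image_volume], casting intensities
#' to double. Inputs with any non-finite voxel are rejected outright rather
#' than silently propagated into subtraction maps.
#'
#' @param path path to a NIfTI-1 file.
#' @return An [image_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1L]
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop("expected a 3-D image, got ", length(d), " dimensions in ", path)
  sp <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  org <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  arr <- array(as.numeric(img), dim = d)
  n_bad <- sum(!is.finite(arr))
  if (n_bad > 0L)
    stop("refusing to load ", path, ": ", n_bad, " non-finite voxel(s)")
  image_volume(arr, spacing = sp, origin = org)
}

#' Write a volume or mask as NIfTI-1
#'
#' Volumes are stored as float32 (round-trip exact to float32 precision,
#' geometry exact); masks as uint8 \{0,1\}.
#'
#' @param vol an [image_volume] or [roi_mask].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  is_mask <- inherits(vol, "roi_mask")
  if (!is_mask && !inherits(vol, "image_volume"))
    stop("'vol' must be an image_volume or roi_mask")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  if (file.access(dir, 2L) != 0L) stop("directory not writable: ", dir)
  arr <- if (is_mask) array(as.numeric(vol$data), dim(vol$data)) else vol$data
  img <- RNifti::asNifti(arr)
  aff <- nifti_affine(vol$spacing, vol$origin)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = if (is_mask) "uint8" else "float")
  invisible(path)
}

#' Read an ROI mask against a reference grid
#'
#' Any nonzero voxel becomes `TRUE`. The mask must live on exactly the
#' reference grid; an all-false mask is accepted at load time (analysis
#' operations reject it later).
#'
#' @param path path to a NIfTI-1 mask.
#' @param reference the [image_volume] defining the expected geometry.
#' @return An [roi_mask].
#' @export
read_mask <- function(path, reference) {
  stopifnot(inherits(reference, "image_volume"))
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L || !identical(as.integer(d), dim(reference$data)))
    stop("mask geometry ", paste(d, collapse = "x"), " @ (",
         paste(signif(RNifti::pixdim(img)[1:3], 6), collapse = ", "),
         ") mm does not match reference ",
         paste(dim(reference$data), collapse = "x"), " @ (",
         paste(signif(reference$spacing, 6), collapse = ", "), ") mm")
  sp <- RNifti::pixdim(img)[1:3]
  if (max(abs(sp - reference$spacing)) > 1e-4)
    stop("mask spacing (", paste(signif(sp, 6), collapse = ", "),
         ") mm does not match reference spacing (",
         paste(signif(reference$spacing, 6), collapse = ", "), ") mm")
  roi_mask(array(as.numeric(img), dim = d) != 0, reference)
}

# world coordinates (mm) of all voxel centres, as an N x 3 matrix in R's
# column-major voxel order
grid_world_coords <- function(vol) {
  d <- dim(vol$data)
  i <- seq_len(d[1]) - 1
  j <- seq_len(d[2]) - 1
  k <- seq_len(d[3]) - 1
  cbind(rep(i, times = d[2] * d[3]) * vol$spacing[1] + vol$origin[1],
        rep(rep(j, each = d[1]), times = d[3]) * vol$spacing[2] + vol$origin[2],
        rep(k, each = d[1] * d[2]) * vol$spacing[3] + vol$origin[3])
}
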