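#' Rigid spatial transform (3 rotations + 3 translations)
#'
#' Parameterised by Euler angles in degrees (applied as
#' `R = Rz %*% Ry %*% Rx`), a translation in mm, and a rotation centre in
#' world coordinates. A transform maps world points as
#' `y = R (x - centre) + centre + translation`. In resampling the transform
#' is used in the pull direction: the output (fixed-space) voxel at point `p`
#' samples the source volume at `transform(p)`.
#'
#' @param rotation numeric length-3, rotations about x, y, z in degrees.
#' @param translation numeric length-3, offsets in mm.
#' @param centre numeric length-3, rotation centre in world mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            centre = c(0, 0, 0)) {
  rotation <- as.numeric(rotation); translation <- as.numeric(translation)
  centre <- as.numeric(centre)
  stopifnot(length(rotation) == 3L, length(translation) == 3L,
            length(centre) == 3L, all(is.finite(c(rotation, translation, centre))))
  structure(list(rotation = rotation, translation = translation,
                 centre = centre),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> rot (", paste(signif(x$rotation, 4), collapse = ", "),
      ") deg, trans (", paste(signif(x$translation, 4), collapse = ", "),
      ") mm\n", sep = "")
  invisible(x)
}

rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

# Euler angles (deg) from a rotation matrix, inverting R = Rz Ry Rx
euler_from_matrix <- function(R) {
  ry <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {                      # gimbal lock: fold everything into rx
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz) * 180 / pi
}

#' 4x4 homogeneous affine matrix of a rigid transform
#' @param transform a [rigid_transform].
#' @return A 4x4 numeric matrix.
#' @export
transform_affine <- function(transform) {
  R <- rotation_matrix(transform$rotation)
  b <- transform$centre + transform$translation -
    R %*% transform$centre
  rbind(cbind(R, b), c(0, 0, 0, 1))
}

transform_from_affine <- function(A, centre = c(0, 0, 0)) {
  R <- A[1:3, 1:3]
  b <- A[1:3, 4]
  rot <- euler_from_matrix(R)
  trans <- as.numeric(b - centre + R %*% centre)
  rigid_transform(rot, trans, centre)
}

#' Apply a rigid transform to world points
#' @param transform a [rigid_transform].
#' @param points N x 3 matrix (or length-3 vector) of world coordinates, mm.
#' @return Transformed points, same shape.
#' @export
apply_transform <- function(transform, points) {
  vec <- is.null(dim(points))
  pts <- if (vec) matrix(points, 1, 3) else points
  A <- transform_affine(transform)
  out <- pts %*% t(A[1:3, 1:3])
  out <- sweep(out, 2, A[1:3, 4], "+")
  if (vec) as.numeric(out) else out
}

#' Invert a rigid transform
#'
#' `compose_transforms(transform, invert_transform(transform))` is the
#' identity to within 1e-6 mm / degrees.
#'
#' @param transform a [rigid_transform].
#' @return The inverse [rigid_transform] (same rotation centre).
#' @export
invert_transform <- function(transform) {
  A <- transform_affine(transform)
  Ri <- t(A[1:3, 1:3])
  bi <- -Ri %*% A[1:3, 4]
  transform_from_affine(rbind(cbind(Ri, bi), c(0, 0, 0, 1)),
                        centre = transform$centre)
}

#' Compose two rigid transforms (`first`, then `second`)
#' @param second,first [rigid_transform] objects.
#' @return The composed [rigid_transform], centred at `second`'s centre.
#' @export
compose_transforms <- function(second, first) {
  A <- transform_affine(second) %*% transform_affine(first)
  transform_from_affine(A, centre = second$centre)
}

is_identity_transform <- function(transform, tol = 1e-12) {
  max(abs(c(transform$rotation, transform$translation))) <= tol
}
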