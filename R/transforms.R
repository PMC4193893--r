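#' Rigid (6 degree-of-freedom) world-coordinate transform
#'
#' A proper rigid-body transform `x' = R x + t` in millimetre world
#' coordinates. The rotation must be orthonormal with determinant +1.
#'
#' @param rotation 3x3 orthonormal rotation matrix.
#' @param translation length-3 translation in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be proper (det = +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Build a rigid transform from Euler angles about a centre
#'
#' Rotations are applied in Z-Y-X order (degrees) about `center`, followed
#' by `translation`: `x' = R (x - c) + c + t`.
#'
#' @param angles_deg rotations about the x, y, z axes in degrees.
#' @param center rotation centre in mm.
#' @param translation translation in mm.
#' @return A `rigid_transform`.
#' @export
rigid_from_euler <- function(angles_deg = c(0, 0, 0), center = c(0, 0, 0),
                             translation = c(0, 0, 0)) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  R <- Rz %*% Ry %*% Rx
  rigid_transform(R, as.numeric(center - R %*% center + translation))
}

#' Apply a rigid transform to points
#' @param transform a `rigid_transform`.
#' @param points n x 3 matrix of mm coordinates (or a length-3 vector).
#' @return Transformed points, same shape.
#' @export
transform_points <- function(transform, points) {
  if (is.null(dim(points))) points <- matrix(points, 1, 3)
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform mapping `x` to
#' `a(b(x))`.
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% transform$translation))
}

#' Rotation angle of a rigid transform
#' @param transform a `rigid_transform`.
#' @return Rotation magnitude in degrees.
#' @export
rotation_angle <- function(transform) {
  ct <- (sum(diag(transform$rotation)) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Represent a rigid transform as a 4x4 affine matrix
#' @param transform a `rigid_transform`.
#' @return A 4x4 homogeneous matrix.
#' @export
as_affine_matrix <- function(transform) {
  m <- diag(4)
  m[1:3, 1:3] <- transform$rotation
  m[1:3, 4] <- transform$translation
  m
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform: rotation", sprintf("%.3f", rotation_angle(x)),
      "deg, translation (",
      paste(sprintf("%.3f", x$translation), collapse = ", "), ") mm\n")
  invisible(x)
}
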