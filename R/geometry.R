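## Rotation and rigid-transform utilities shared by all reconstruction stages.
##
## Convention (see the methods vignette): poses are intrinsic ZYZ Euler angles
## (rot, tilt, psi) in degrees.  The pose matrix
##     R = Rz(psi) %*% Ry(tilt) %*% Rz(rot)
## maps reference-frame coordinates to particle-frame coordinates
## (x_particle = R %*% x_reference); projection integrates along +z of the
## particle frame.  Symmetry expansion composes on the right: R_k = R %*% S_k.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Normalize angles to the canonical range (-180, 180]
#'
#' @param a numeric vector of angles in degrees.
#' @return angles wrapped into (-180, 180]. Idempotent.
#' @export
normalize_angle <- function(a) {
  a <- a %% 360
  a[a > 180] <- a[a > 180] - 360
  a
}

rot_z <- function(deg) {
  t <- deg2rad(deg); c <- cos(t); s <- sin(t)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

rot_y <- function(deg) {
  t <- deg2rad(deg); c <- cos(t); s <- sin(t)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' Euler angles to rotation matrix
#'
#' Intrinsic ZYZ convention: `R = Rz(psi) Ry(tilt) Rz(rot)` mapping the
#' reference frame to the particle projection frame.
#'
#' @param rot,tilt,psi Euler angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(rot, tilt, psi) {
  rot_z(psi) %*% rot_y(tilt) %*% rot_z(rot)
}

#' Rotation matrix to Euler angles
#'
#' Inverse of [euler_to_matrix()]. Degenerate poses (tilt near 0 or 180)
#' return psi = 0 and fold the in-plane rotation into rot.
#'
#' @param R 3x3 rotation matrix.
#' @return named numeric vector (rot, tilt, psi) in degrees, tilt in
#'   \[0, 180\], rot and psi in (-180, 180\].
#' @export
matrix_to_euler <- function(R) {
  ct <- max(-1, min(1, R[3, 3]))
  tilt <- rad2deg(acos(ct))
  if (abs(ct) > 1 - 1e-12) {
    ## tilt ~ 0 (R = Rz(psi + rot)) or ~180: report a single z-rotation
    rot <- rad2deg(atan2(R[2, 1], R[1, 1]))
    if (ct < 0) rot <- -rot
    psi <- 0
  } else {
    psi <- rad2deg(atan2(R[2, 3], R[1, 3]))
    rot <- rad2deg(atan2(R[3, 2], -R[3, 1]))
  }
  c(rot = normalize_angle(rot), tilt = tilt, psi = normalize_angle(psi))
}

#' Rotation about an arbitrary axis
#'
#' Rodrigues rotation by `angle` degrees about `axis` (need not be unit).
#'
#' @param axis length-3 numeric vector.
#' @param angle degrees.
#' @return 3x3 rotation matrix.
#' @export
axis_rotation <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  t <- deg2rad(angle); c <- cos(t); s <- sin(t)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + s * K + (1 - c) * (K %*% K)
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with det +1.
#' @param translation length-3 numeric vector in Angstrom.
#' @return object of class `transform_rt`.
#' @export
transform_rt <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be proper (det = +1)")
  structure(list(rotation = rotation,
                 translation = as.numeric(translation)),
            class = "transform_rt")
}

#' Compose rigid transforms
#'
#' `compose_rt(a, b)` applies `b` first, then `a`.
#' @param a,b `transform_rt` objects.
#' @return `transform_rt`.
#' @export
compose_rt <- function(a, b) {
  transform_rt(a$rotation %*% b$rotation,
               as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param rt `transform_rt`.
#' @return `transform_rt`.
#' @export
invert_rt <- function(rt) {
  transform_rt(t(rt$rotation), as.numeric(-t(rt$rotation) %*% rt$translation))
}

#' Apply a rigid transform to coordinates
#'
#' @param rt `transform_rt`.
#' @param x n x 3 matrix (or length-3 vector) of coordinates in Angstrom.
#' @return transformed coordinates, same shape as input.
#' @export
apply_rt <- function(rt, x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, 1, 3)
  out <- x %*% t(rt$rotation)
  out <- sweep(out, 2, rt$translation, "+")
  if (vec) as.numeric(out) else out
}

#' @export
print.transform_rt <- function(x, ...) {
  e <- matrix_to_euler(x$rotation)
  cat(sprintf("rigid transform: rot %.2f tilt %.2f psi %.2f deg, t = (%.2f, %.2f, %.2f) A\n",
              e[1], e[2], e[3],
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}
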