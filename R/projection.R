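## Forward projection: line integrals of a density volume along the +z axis
## of the rotated (particle) frame.  Two independent routes are provided:
## the Fourier central-slice route (production) and real-space summation of
## the trilinearly rotated volume (slow, used as a cross-check oracle).
## Images are physical line integrals: voxel sums times the pixel size.

pose_matrix <- function(pose) {
  if (is.matrix(pose)) pose
  else euler_to_matrix(pose[["rot"]], pose[["tilt"]], pose[["psi"]])
}

#' Project a volume along a pose
#'
#' The projected reference is displaced by `-shift` in the image (the
#' particle-table shift convention: `shift` is the translation that would
#' re-center the particle).
#'
#' @param volume [volume_grid()].
#' @param pose either a 3x3 rotation matrix (reference -> particle frame) or
#'   a named vector/list with rot, tilt, psi in degrees.
#' @param shift length-2 translation in Angstrom.
#' @param method "fourier" (central slice) or "real" (rotate and sum).
#' @param oversample zero-padding factor for the Fourier route; 2 keeps the
#'   trilinear slice interpolation accurate for smooth densities, 1 samples
#'   the native grid (the exact adjoint of [backproject()]).
#' @return n x n image matrix in density * Angstrom units.
#' @export
project_volume <- function(volume, pose, shift = c(0, 0),
                           method = c("fourier", "real"), oversample = 2) {
  method <- match.arg(method)
  R <- pose_matrix(pose)
  n <- dim(volume$data)[1]
  px <- volume$pixel_size
  if (method == "fourier") {
    fv <- fftc_padded(volume$data, oversample)
    sl <- cpp_slice_extract(fv, array(R, c(3, 3, 1)), n, oversample)[, , 1]
    if (any(shift != 0))
      sl <- sl * shift_phase(n, -shift[1] / px, -shift[2] / px)
    Re(ifftc(sl)) * px
  } else {
    w <- cpp_resample(volume$data, R, c(-shift[1] / px, -shift[2] / px, 0), n)
    apply(w, c(1, 2), sum) * px
  }
}

#' Project a volume at many poses
#'
#' Batch form of [project_volume()] (Fourier route), computing the 3D
#' transform once.
#'
#' @param volume [volume_grid()].
#' @param table [particle_table()] supplying poses and shifts.
#' @param oversample zero-padding factor (see [project_volume()]).
#' @return [image_stack()] of noiseless, CTF-free projections.
#' @export
project_stack <- function(volume, table, oversample = 2) {
  n <- dim(volume$data)[1]
  px <- volume$pixel_size
  fv <- fftc_padded(volume$data, oversample)
  rots <- vapply(seq_len(nrow(table)), function(i)
    euler_to_matrix(table$rot[i], table$tilt[i], table$psi[i]),
    matrix(0, 3, 3))
  slices <- cpp_slice_extract(fv, rots, n, oversample)
  out <- array(0, c(n, n, nrow(table)))
  for (i in seq_len(nrow(table))) {
    sl <- slices[, , i]
    if (table$shift_x[i] != 0 || table$shift_y[i] != 0)
      sl <- sl * shift_phase(n, -table$shift_x[i] / px,
                             -table$shift_y[i] / px)
    out[, , i] <- Re(ifftc(sl)) * px
  }
  image_stack(out, px)
}

#' Backproject an image along a pose
#'
#' Adjoint of [project_volume()] (Fourier route) up to interpolation error:
#' `<project(v, p), img> ~ <v, backproject(img, p)>`.
#'
#' @param image n x n matrix.
#' @param pose rotation matrix or (rot, tilt, psi).
#' @param pixel_size Angstrom per pixel.
#' @return [volume_grid()].
#' @export
backproject <- function(image, pose, pixel_size) {
  R <- pose_matrix(pose)
  n <- nrow(image)
  fi <- fftc(image)
  ins <- cpp_fourier_insert(array(fi, c(n, n, 1)),
                            array(1, c(n, n, 1)),
                            array(R, c(3, 3, 1)))
  volume_grid(Re(ifftc(ins$num)) * n * pixel_size, pixel_size)
}
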