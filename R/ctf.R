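## Weak-phase contrast transfer function.

#' CTF parameter set
#'
#' @param defocus_u,defocus_v defocus along the major/minor astigmatism axes
#'   in Angstrom (positive = underfocus).
#' @param astig_angle azimuth of the defocus_u axis, degrees.
#' @param voltage acceleration voltage in kV.
#' @param cs spherical aberration in mm.
#' @param amplitude_contrast amplitude-contrast fraction in \[0, 1\].
#' @param phase_shift additional phase shift in degrees (phase plate).
#' @return object of class `ctf_params`.
#' @export
ctf_params <- function(defocus_u, defocus_v = defocus_u, astig_angle = 0,
                       voltage = 300, cs = 2.7, amplitude_contrast = 0.1,
                       phase_shift = 0) {
  stopifnot(defocus_u > 0, defocus_v > 0, voltage > 0,
            amplitude_contrast >= 0, amplitude_contrast <= 1)
  structure(list(defocus_u = defocus_u, defocus_v = defocus_v,
                 astig_angle = astig_angle, voltage = voltage, cs = cs,
                 amplitude_contrast = amplitude_contrast,
                 phase_shift = phase_shift),
            class = "ctf_params")
}

#' Relativistic electron wavelength
#' @param voltage acceleration voltage in kV.
#' @return wavelength in Angstrom (0.0197 A at 300 kV).
#' @export
electron_wavelength <- function(voltage) {
  u <- voltage * 1000
  12.2643247 / sqrt(u * (1 + u * 0.978466e-6))
}

#' Evaluate the CTF on an image frequency grid
#'
#' Weak-phase model
#' `CTF(f, a) = -(sqrt(1 - A^2) sin(g) + A cos(g))` with
#' `g = pi lambda z(a) f^2 - (pi/2) Cs lambda^3 f^4 + phase`, astigmatic
#' defocus `z(a) = (zu + zv)/2 + (zu - zv)/2 cos(2 (a - astig))`.
#' At f = 0 the transfer is exactly `-A`.
#'
#' @param params [ctf_params()].
#' @param n image box size in pixels.
#' @param pixel_size pixel size in Angstrom.
#' @return n x n matrix of transfer values on the centered frequency grid.
#' @export
evaluate_ctf <- function(params, n, pixel_size) {
  stopifnot(pixel_size > 0)
  k <- freq_axis(n) / (n * pixel_size)       # 1/A
  kx <- matrix(k, n, n)
  ky <- matrix(k, n, n, byrow = TRUE)
  f2 <- kx^2 + ky^2
  az <- atan2(ky, kx)
  lam <- electron_wavelength(params$voltage)
  zu <- params$defocus_u; zv <- params$defocus_v
  z <- 0.5 * (zu + zv) +
       0.5 * (zu - zv) * cos(2 * (az - deg2rad(params$astig_angle)))
  cs_a <- params$cs * 1e7                    # mm -> A
  g <- pi * lam * z * f2 - 0.5 * pi * cs_a * lam^3 * f2^2 +
       deg2rad(params$phase_shift)
  A <- params$amplitude_contrast
  -(sqrt(1 - A^2) * sin(g) + A * cos(g))
}

ctf_from_row <- function(row, n, pixel_size, voltage = 300, cs = 2.7,
                         amplitude_contrast = 0.1) {
  evaluate_ctf(ctf_params(row$defocus_u, row$defocus_v, row$astig_angle,
                          voltage = voltage, cs = cs,
                          amplitude_contrast = amplitude_contrast),
               n, pixel_size)
}
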