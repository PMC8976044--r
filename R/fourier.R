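## Centered FFT helpers.  All Fourier-domain arrays in this package are
## "centered": DC sits at 0-based index N/2 along every dimension and the
## transform is taken about the grid-center spatial origin, so that the
## central-slice relation P(k) = V(R^T k) holds without phase ramps.

fftshift <- function(a) {
  d <- dim(a)
  if (is.null(d)) d <- length(a)
  idx <- lapply(d, function(n) ((seq_len(n) - 1 - n %/% 2) %% n) + 1)
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

## (-1)^(fx + fy [+ fz]) sign array for centered frequencies
freq_sign <- function(d) {
  f <- lapply(d, function(n) (seq_len(n) - 1 - n %/% 2))
  s <- Reduce(`+`, lapply(seq_along(d), function(i) {
    perm <- rep(1, length(d)); perm[i] <- d[i]
    aperm(array(f[[i]], dim = c(d[i], d[-i])),
          order(c(i, seq_along(d)[-i])))
  }))
  1 - 2 * (abs(s) %% 2)
}

## centered forward transform (2D or 3D)
fftc <- function(a) {
  s <- freq_sign(dim(a))
  fftshift(stats::fft(a)) * s
}

## centered inverse transform; returns a complex array
ifftc <- function(a) {
  s <- freq_sign(dim(a))
  stats::fft(fftshift(a * s), inverse = TRUE) / length(a)
}

## centered transform of a volume zero-padded to os * N per side; padding
## refines the Fourier sampling so trilinear slice interpolation of smooth
## densities stays accurate
fftc_padded <- function(a, os = 1) {
  if (os == 1) return(fftc(a))
  n <- dim(a)[1]
  m <- as.integer(os * n)
  big <- array(0, c(m, m, m))
  idx <- (m - n) / 2 + seq_len(n)
  big[idx, idx, idx] <- a
  fftc(big)
}

## centered integer frequency axis for an even grid
freq_axis <- function(n) seq_len(n) - 1 - n %/% 2

## Fourier-domain translation: multiply a centered 2D transform by the
## phase that translates the image by (dx, dy) pixels.
shift_phase <- function(n, dx, dy) {
  k <- freq_axis(n)
  px <- exp(-2i * pi * k * dx / n)
  py <- exp(-2i * pi * k * dy / n)
  outer(px, py)
}
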