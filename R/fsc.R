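## Fourier shell correlation between two volumes and threshold-crossing
## resolution estimation.

#' Fourier shell correlation between two volumes
#'
#' Per-shell normalized cross-correlation of centered Fourier coefficients,
#' in shells of one reciprocal voxel, up to Nyquist.  Symmetric in its
#' arguments and invariant to a global scale of either volume.
#'
#' @param vol_a,vol_b [volume_grid()] on identical grids.
#' @param mask optional real-space mask ([volume_grid()] or array) applied
#'   to both volumes before the transform.
#' @return data.frame of class `fsc_curve` with columns freq (1/Angstrom,
#'   shell centers), fsc, n_voxels; pixel size kept as an attribute.
#' @export
compute_fsc <- function(vol_a, vol_b, mask = NULL) {
  a <- vol_a$data; b <- vol_b$data
  if (!all(dim(a) == dim(b)))
    stop("volumes have different grid sizes")
  if (abs(vol_a$pixel_size - vol_b$pixel_size) > 1e-9 * vol_a$pixel_size)
    stop("volumes have different pixel sizes")
  if (!is.null(mask)) {
    m <- if (inherits(mask, "volume_grid")) mask$data else mask
    a <- a * m; b <- b * m
  }
  n <- dim(a)[1]
  fa <- fftc(a); fb <- fftc(b)
  f <- freq_axis(n)
  r2 <- outer(outer(f^2, f^2, `+`), f^2, `+`)
  shell <- round(sqrt(r2))
  keep <- shell <= n %/% 2 & shell >= 1
  sh <- shell[keep]
  num <- Re(fa[keep] * Conj(fb[keep]))
  pa <- Mod(fa[keep])^2
  pb <- Mod(fb[keep])^2
  s_num <- tapply(num, sh, sum)
  s_pa <- tapply(pa, sh, sum)
  s_pb <- tapply(pb, sh, sum)
  n_vox <- as.integer(table(sh))
  shells <- as.integer(names(s_num))
  fsc <- as.numeric(s_num / sqrt(s_pa * s_pb))
  fsc[!is.finite(fsc)] <- 0
  out <- data.frame(freq = shells / (n * vol_a$pixel_size), fsc = fsc,
                    n_voxels = n_vox)
  attr(out, "pixel_size") <- vol_a$pixel_size
  class(out) <- c("fsc_curve", "data.frame")
  out
}

#' Resolution at an FSC threshold
#'
#' 1/frequency at the first crossing below `threshold`, linearly
#' interpolated between shells.  Never reports finer than the Nyquist
#' limit of 2 x pixel size; a curve that never crosses reports exactly
#' that limit.
#'
#' @param curve [compute_fsc()] output.
#' @param threshold FSC criterion (0.143 gold-standard default).
#' @return resolution in Angstrom.
#' @export
resolution_at <- function(curve, threshold = 0.143) {
  px <- attr(curve, "pixel_size")
  nyq <- 2 * px
  below <- which(curve$fsc < threshold)
  if (!length(below)) return(nyq)
  i <- below[1]
  if (i == 1) return(Inf)  # drops below threshold in the first shell
  f0 <- curve$freq[i - 1]; f1 <- curve$freq[i]
  v0 <- curve$fsc[i - 1]; v1 <- curve$fsc[i]
  fc <- f0 + (v0 - threshold) / (v0 - v1) * (f1 - f0)
  max(1 / fc, nyq)
}

#' Write an FSC curve as TSV
#' @param curve [compute_fsc()] output.
#' @param path output file (columns freq, fsc, n_voxels).
#' @export
write_fsc_tsv <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
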