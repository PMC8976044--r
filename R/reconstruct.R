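## Wiener-weighted direct Fourier inversion.  Each particle image is
## re-centered by its shift, transformed, premultiplied by its CTF and
## inserted as a central slice; the volume is num / (den + eps) with
## num = sum(CTF * F), den = sum(CTF^2), eps a small fraction of the mean
## nonzero CTF^2 weight to tame division at CTF zeros.

#' Reconstruct a volume from a particle stack
#'
#' @param stack [image_stack()]; slices are addressed by the table's
#'   `image_index` column, so a symmetry-expanded table may reference each
#'   image several times.
#' @param table [particle_table()] with poses, shifts and CTF parameters.
#' @param half_sets if TRUE return two reconstructions from disjoint
#'   even/odd record subsets (gold-standard halves) instead of one.
#' @param eps_frac Wiener constant as a fraction of the mean nonzero
#'   CTF^2 weight.
#' @param voltage,cs,amplitude_contrast global CTF parameters.
#' @param ctf if FALSE, insert with CTF = 1 (for CTF-free toy stacks).
#' @return a [volume_grid()], or a list(half1, half2) when `half_sets`.
#' @export
reconstruct <- function(stack, table, half_sets = FALSE, eps_frac = 0.01,
                        voltage = 300, cs = 2.7, amplitude_contrast = 0.1,
                        ctf = TRUE) {
  n <- dim(stack$data)[1]
  px <- stack$pixel_size
  if (half_sets) {
    idx <- seq_len(nrow(table))
    halves <- list(idx[idx %% 2 == 1], idx[idx %% 2 == 0])
    if (any(lengths(halves) < 2))
      stop("need at least 2 particles per half-set")
    return(lapply(halves, function(h)
      reconstruct(stack, table[h, , drop = FALSE], half_sets = FALSE,
                  eps_frac = eps_frac, voltage = voltage, cs = cs,
                  amplitude_contrast = amplitude_contrast, ctf = ctf)))
  }
  p <- nrow(table)
  if (p < 1) stop("empty particle table")
  if (max(table$image_index) > dim(stack$data)[3])
    stop("table references image ", max(table$image_index),
         " beyond stack of ", dim(stack$data)[3])
  num <- array(0i, c(n, n, n))
  den <- array(0, c(n, n, n))
  chunk <- max(1L, min(p, as.integer(2^25 / (n * n))))
  for (lo in seq(1L, p, by = chunk)) {
    hi <- min(p, lo + chunk - 1L)
    m <- hi - lo + 1L
    slices <- array(0i, c(n, n, m))
    ctfs <- array(1, c(n, n, m))
    rots <- array(0, c(3, 3, m))
    for (j in seq_len(m)) {
      i <- lo + j - 1L
      img <- stack$data[, , table$image_index[i]] / px
      fi <- fftc(img)
      if (table$shift_x[i] != 0 || table$shift_y[i] != 0)
        fi <- fi * shift_phase(n, table$shift_x[i] / px,
                               table$shift_y[i] / px)
      slices[, , j] <- fi
      if (ctf)
        ctfs[, , j] <- ctf_from_row(table[i, ], n, px, voltage, cs,
                                    amplitude_contrast)
      rots[, , j] <- euler_to_matrix(table$rot[i], table$tilt[i],
                                     table$psi[i])
    }
    ins <- cpp_fourier_insert(slices, ctfs, rots)
    num <- num + ins$num
    den <- den + ins$den
  }
  eps <- eps_frac * mean(den[den > 0])
  vol <- Re(ifftc(num / (den + eps)))
  volume_grid(vol, px)
}
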