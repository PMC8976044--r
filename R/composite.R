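## Composite ring assembly: fit one refined subunit into each of the n_sym
## ring positions, replicate the subunit model, and measure ring geometry.

#' Ring placement
#'
#' One rigid transform per subunit position (subunit frame -> ring frame).
#'
#' @param transforms list of [transform_rt()], length n_sym.
#' @param n_sym symmetry order.
#' @param axis ring axis.
#' @param scores optional per-position fit correlations.
#' @return object of class `ring_placement`.
#' @export
ring_placement <- function(transforms, n_sym = length(transforms),
                           axis = c(0, 0, 1), scores = NULL) {
  if (length(transforms) != n_sym)
    stop("need exactly n_sym transforms")
  structure(list(transforms = transforms, n_sym = as.integer(n_sym),
                 axis = axis / sqrt(sum(axis^2)), scores = scores),
            class = "ring_placement")
}

#' Assemble a composite ring model
#'
#' Places n_sym transformed copies of the subunit model; chain ids are
#' suffixed with the subunit index.  No clash checking is performed.
#'
#' @param model subunit [atomic_model()].
#' @param placement [ring_placement()].
#' @return composite [atomic_model()] with n_sym x the input atoms (the
#'   degenerate single-identity placement returns the input unchanged).
#' @export
assemble_ring <- function(model, placement) {
  tr <- placement$transforms
  if (length(tr) == 1 &&
      max(abs(tr[[1]]$rotation - diag(3))) < 1e-12 &&
      max(abs(tr[[1]]$translation)) < 1e-12)
    return(model)
  parts <- lapply(seq_along(tr), function(k) {
    m <- transform_model(model, tr[[k]])
    sfx <- function(ch) sprintf("%s_%d", ch, k - 1)
    m$atoms$chain <- sfx(m$atoms$chain)
    m$chains$chain <- sfx(m$chains$chain)
    if (!is.null(m$sse)) m$sse$chain <- sfx(m$sse$chain)
    m
  })
  atomic_model(do.call(rbind, lapply(parts, `[[`, "atoms")),
               do.call(rbind, lapply(parts, `[[`, "chains")),
               if (!is.null(model$sse))
                 do.call(rbind, lapply(parts, `[[`, "sse")))
}

## masked local correlation between the placed subunit and the ring,
## evaluated over the subunit's support inside its bounding box
placement_cor <- function(ring, sub, R, t_vox) {
  nr <- dim(ring$data)[1]
  ns <- dim(sub$data)[1]
  placed <- cpp_resample(sub$data, R, t_vox, nr)
  ctr <- round(t_vox) + nr %/% 2            # 0-based box center
  rng <- lapply(ctr, function(c0)
    max(1, c0 - ns %/% 2 + 1):min(nr, c0 + ns %/% 2))
  pw <- placed[rng[[1]], rng[[2]], rng[[3]]]
  rw <- ring$data[rng[[1]], rng[[2]], rng[[3]]]
  sel <- pw > 0.05 * max(sub$data)
  if (sum(sel) < 10) return(0)
  stats::cor(pw[sel], rw[sel])
}

#' Fit a subunit volume into each ring position
#'
#' For every k in 0..n_sym-1, searches a rotation about the axis near
#' k * 360 / n_sym (within `angle_window`, refined to sub-degree accuracy)
#' and a small in-plane translation around the nominal subunit center,
#' maximizing the masked real-space correlation between the placed subunit
#' volume and the ring volume.
#'
#' @param subunit_volume [volume_grid()] (subunit centered at the origin).
#' @param ring_volume [volume_grid()] on the same pixel size.
#' @param n_sym symmetry order.
#' @param axis ring axis.
#' @param center nominal subunit-0 center in the ring frame (Angstrom); if
#'   NULL, the radial center of mass of the ring density is used.
#' @param angle_window,angle_step search window and step about each nominal
#'   angle, degrees.
#' @param trans_window,trans_step in-plane translation search, Angstrom.
#' @param cor_floor placements scoring below this correlation are flagged.
#' @return [ring_placement()] with per-position scores; unreliable
#'   positions are reported in the `unreliable` attribute.
#' @export
fit_subunit_positions <- function(subunit_volume, ring_volume, n_sym,
                                  axis = c(0, 0, 1), center = NULL,
                                  angle_window = 10, angle_step = 2,
                                  trans_window = 3, trans_step = 1.5,
                                  cor_floor = 0.5) {
  px <- ring_volume$pixel_size
  if (abs(subunit_volume$pixel_size - px) > 1e-9 * px)
    stop("subunit and ring pixel sizes differ")
  nr <- dim(ring_volume$data)[1]
  if (is.null(center)) {
    ## radial center of mass in the xy plane; subunit 0 on +x by convention
    ax <- (seq_len(nr) - 1 - nr %/% 2) * px
    rho <- pmax(ring_volume$data, 0)
    rxy <- sqrt(outer(ax^2, ax^2, `+`))
    wxy <- apply(rho, c(1, 2), sum)
    center <- c(sum(wxy * rxy) / sum(wxy), 0, 0)
  }
  dtr <- seq(-trans_window, trans_window, by = trans_step)
  transforms <- vector("list", n_sym)
  scores <- numeric(n_sym)
  if (n_sym == 1) angle_window <- max(angle_window, angle_step)
  for (k in seq_len(n_sym) - 1L) {
    nominal <- k * 360 / n_sym
    score_at <- function(theta, dx, dy) {
      R <- axis_rotation(axis, theta)
      t_A <- as.numeric(R %*% center) + c(dx, dy, 0)
      placement_cor(ring_volume, subunit_volume, R, t_A / px)
    }
    grid <- expand.grid(theta = nominal + seq(-angle_window, angle_window,
                                              by = angle_step),
                        dx = dtr, dy = dtr, KEEP.OUT.ATTRS = FALSE)
    vals <- mapply(score_at, grid$theta, grid$dx, grid$dy)
    b <- which.max(vals)
    ## sub-degree refinement of the rotation at the best translation
    opt <- stats::optimize(function(th) score_at(th, grid$dx[b], grid$dy[b]),
                           lower = grid$theta[b] - angle_step,
                           upper = grid$theta[b] + angle_step, maximum = TRUE,
                           tol = 1e-3)
    R <- axis_rotation(axis, opt$maximum)
    t_A <- as.numeric(R %*% center) + c(grid$dx[b], grid$dy[b], 0)
    transforms[[k + 1]] <- transform_rt(R, t_A)
    scores[k + 1] <- opt$objective
  }
  pl <- ring_placement(transforms, n_sym, axis, scores)
  attr(pl, "unreliable") <- which(scores < cor_floor)
  if (any(scores < cor_floor))
    warning(sum(scores < cor_floor), " placement(s) below correlation floor ",
            cor_floor)
  pl
}

#' Ring diameters from a composite model
#'
#' Radial CA distances from the axis (through the origin): inner = 2 x min,
#' outer = 2 x max, plus a 1st/99th-percentile variant robust to stray
#' atoms.
#'
#' @param model composite [atomic_model()].
#' @param axis ring axis.
#' @return list(inner, outer, inner_robust, outer_robust) in Angstrom.
#' @export
ring_diameters <- function(model, axis = c(0, 0, 1)) {
  if (nrow(model$chains) < 2)
    warning("single-subunit model: diameters reflect one wedge only")
  axis <- axis / sqrt(sum(axis^2))
  ca <- model_ca(model)
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  axial <- xyz %*% axis
  rad <- sqrt(pmax(rowSums(xyz^2) - as.numeric(axial)^2, 0))
  list(inner = 2 * min(rad), outer = 2 * max(rad),
       inner_robust = 2 * as.numeric(stats::quantile(rad, 0.01)),
       outer_robust = 2 * as.numeric(stats::quantile(rad, 0.99)))
}
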