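## Block-based (subparticle) processing: symmetry expansion of ring
## particles, re-centering of a chosen subunit with defocus bookkeeping,
## window extraction, and confined exhaustive local refinement.

#' Subunit frame
#'
#' @param center subunit center in the ring reference frame, Angstrom; must
#'   not lie on the symmetry axis (or the n_sym subunits coincide).
#' @param n_sym cyclic symmetry order.
#' @param axis symmetry axis.
#' @param check set FALSE to allow a purely axial center (useful for
#'   exercising the defocus bookkeeping in isolation).
#' @return object of class `subunit_frame`.
#' @export
subunit_frame <- function(center, n_sym = 8, axis = c(0, 0, 1),
                          check = TRUE) {
  axis <- axis / sqrt(sum(axis^2))
  radial <- center - sum(center * axis) * axis
  if (check && sqrt(sum(radial^2)) < 1e-6)
    stop("subunit center lies on the symmetry axis; subunits would coincide")
  structure(list(center = as.numeric(center), n_sym = as.integer(n_sym),
                 axis = axis),
            class = "subunit_frame")
}

#' Symmetry-expand a particle table
#'
#' Each record becomes n_sym records with pose R_k = R S_k, where S_k is
#' the rotation by k * 360 / n_sym about the axis (applied in the reference
#' frame, i.e. composed on the right); shifts and defocus are copied and
#' subunit_index is set to k.
#'
#' @param table [particle_table()].
#' @param n_sym symmetry order (1 returns the table unchanged).
#' @param axis symmetry axis.
#' @return expanded [particle_table()] with nrow x n_sym records.
#' @export
symmetry_expand <- function(table, n_sym, axis = c(0, 0, 1)) {
  stopifnot(n_sym >= 1)
  if (n_sym == 1) return(table)
  sym_mats <- lapply(seq_len(n_sym) - 1L, function(k)
    axis_rotation(axis, k * 360 / n_sym))
  out <- table[rep(seq_len(nrow(table)), each = n_sym), , drop = FALSE]
  ang <- matrix(0, nrow(out), 3)
  for (i in seq_len(nrow(table))) {
    R <- euler_to_matrix(table$rot[i], table$tilt[i], table$psi[i])
    for (k in seq_len(n_sym)) {
      e <- matrix_to_euler(R %*% sym_mats[[k]])
      ang[(i - 1) * n_sym + k, ] <- e
    }
  }
  out$rot <- ang[, 1]; out$tilt <- ang[, 2]; out$psi <- ang[, 3]
  out$subunit_index <- rep(seq_len(n_sym) - 1L, nrow(table))
  rownames(out) <- NULL
  attr(out, "bin_level") <- attr(table, "bin_level")
  class(out) <- c("particle_table", "data.frame")
  out
}

#' Re-center subparticles on a subunit
#'
#' For each (already symmetry-expanded) record with pose R_k, the subunit
#' center c projects into the particle frame at q = R_k c.  The in-plane
#' components update the shifts (new shift = old shift - q_xy, split into
#' an integer window offset in pixels and a fractional remainder kept in
#' the shift fields); the axial component updates the defocus
#' (defocus + q_z: +z of the particle frame points away from the focal
#' plane, toward larger underfocus).  Records whose subunit center falls
#' outside the particle box are flagged and excluded (count reported via
#' a message and the `n_excluded` attribute).
#'
#' @param table symmetry-expanded [particle_table()].
#' @param frame [subunit_frame()].
#' @param box_n source particle box size in pixels (for the bounds check).
#' @return [particle_table()] with updated shifts/defocus and integer
#'   `offset_x`, `offset_y` columns (extraction window offsets, pixels).
#' @export
recenter_subparticles <- function(table, frame, box_n) {
  n <- nrow(table)
  px <- table$pixel_size[1]
  q <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    R <- euler_to_matrix(table$rot[i], table$tilt[i], table$psi[i])
    q[i, ] <- as.numeric(R %*% frame$center)
  }
  new_sx <- table$shift_x - q[, 1]
  new_sy <- table$shift_y - q[, 2]
  ox <- round(new_sx / px)
  oy <- round(new_sy / px)
  out <- table
  out$shift_x <- new_sx - ox * px
  out$shift_y <- new_sy - oy * px
  out$offset_x <- as.integer(ox)
  out$offset_y <- as.integer(oy)
  out$defocus_u <- table$defocus_u + q[, 3]
  out$defocus_v <- table$defocus_v + q[, 3]
  half <- box_n / 2
  bad <- abs(ox) >= half | abs(oy) >= half
  if (any(bad)) {
    message(sum(bad), " subparticle(s) project outside the particle box; excluded")
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_excluded") <- sum(bad)
  attr(out, "bin_level") <- attr(table, "bin_level")
  class(out) <- c("particle_table", "data.frame")
  out
}

#' Extract subparticle windows
#'
#' Cuts a `box` x `box` window per record, centered at the source image
#' center minus the record's integer offset; regions outside the source
#' are padded with the source image mean.  Image references are rewritten
#' to the new stack.
#'
#' @param stack source [image_stack()].
#' @param table re-centered [particle_table()] with offset columns.
#' @param box subparticle box size in pixels (<= source box).
#' @return list(stack = [image_stack()], table = updated
#'   [particle_table()]); the `n_padded` attribute of the stack counts
#'   windows that needed padding.
#' @export
extract_subparticles <- function(stack, table, box) {
  n <- dim(stack$data)[1]
  if (box > n) stop("subparticle box (", box, ") exceeds source box (", n, ")")
  if (is.null(table$offset_x))
    stop("table has no offset columns; run recenter_subparticles() first")
  np <- nrow(table)
  out <- array(0, c(box, box, np))
  n_padded <- 0L
  for (i in seq_len(np)) {
    src <- stack$data[, , table$image_index[i]]
    ## window center (0-based) = N/2 - offset; box covers center-box/2 ..
    cx <- n %/% 2 - table$offset_x[i]
    cy <- n %/% 2 - table$offset_y[i]
    xs <- (cx - box %/% 2) + seq_len(box)        # 1-based source columns
    ys <- (cy - box %/% 2) + seq_len(box)
    inx <- xs >= 1 & xs <= n
    iny <- ys >= 1 & ys <= n
    win <- matrix(mean(src), box, box)
    win[inx, iny] <- src[xs[inx], ys[iny]]
    if (!all(inx) || !all(iny)) n_padded <- n_padded + 1L
    out[, , i] <- win
  }
  if (n_padded > 0)
    message(n_padded, " subparticle window(s) extended past the source image; mean-padded")
  tab <- table
  tab$source_image <- table$image_index   # provenance: source particle
  tab$image_name <- "subparticles.mrcs"
  tab$image_index <- seq_len(np)
  st <- image_stack(out, stack$pixel_size)
  attr(st, "n_padded") <- n_padded
  list(stack = st, table = tab)
}

#' Confined local refinement by exhaustive grid search
#'
#' For every record, searches the grid (drot, dtilt, dpsi) in
#' `seq(-angular_range, angular_range, angular_step)` crossed with shifts
#' in `seq(-shift_range, shift_range, shift_step)` around the current
#' parameters.  The score is the normalized cross-correlation (computed in
#' Fourier space, DC excluded) between the particle and the CTF-filtered
#' central-slice projection of the reference.  The arg-max wins; exact
#' score ties break toward the smallest perturbation norm, then
#' lexicographically, so runs are bit-stable.  Additional rounds repeat
#' the search centered on the previous optimum with halved steps.
#'
#' @param stack [image_stack()] of (sub)particles.
#' @param reference [volume_grid()] on the same pixel size and box.
#' @param table [particle_table()].
#' @param angular_range,angular_step degrees.
#' @param shift_range,shift_step Angstrom.
#' @param rounds number of search rounds (steps halve each round).
#' @param mask_radius optional soft circular mask radius (Angstrom) applied
#'   to each particle before scoring.  Essential for subparticle windows
#'   that contain density of neighboring subunits the reference cannot
#'   explain.
#' @param voltage,cs,amplitude_contrast global CTF parameters.
#' @return [particle_table()] with refined poses/shifts and an `ncc` score
#'   column.
#' @export
local_refine <- function(stack, reference, table, angular_range,
                         angular_step, shift_range, shift_step, rounds = 1,
                         mask_radius = NULL, voltage = 300, cs = 2.7,
                         amplitude_contrast = 0.1) {
  stopifnot(angular_range >= 0, angular_step > 0,
            shift_range >= 0, shift_step > 0)
  n <- dim(stack$data)[1]
  px <- stack$pixel_size
  if (abs(reference$pixel_size - px) > 1e-9 * px)
    stop("reference and stack pixel sizes differ")
  if (dim(reference$data)[1] != n)
    stop("reference and stack box sizes differ")
  fv <- fftc_padded(reference$data, 2)
  dc <- c(n %/% 2 + 1, n %/% 2 + 1)
  img_mask <- if (is.null(mask_radius)) NULL
              else soft_disc_mask(n, mask_radius / px, width_px = 3)
  out <- table
  out$ncc <- NA_real_
  for (round in seq_len(rounds)) {
    astep <- angular_step / 2^(round - 1)
    sstep <- shift_step / 2^(round - 1)
    arange <- if (round == 1) angular_range else astep
    srange <- if (round == 1) shift_range else sstep
    da <- seq(-arange, arange, by = astep)
    ds <- seq(-srange, srange, by = sstep)
    if (!length(da) || !length(ds)) stop("empty search grid")
    ang_grid <- expand.grid(drot = da, dtilt = da, dpsi = da,
                            KEEP.OUT.ATTRS = FALSE)
    shift_grid <- expand.grid(dx = ds, dy = ds, KEEP.OUT.ATTRS = FALSE)
    na <- nrow(ang_grid); ns <- nrow(shift_grid)
    ## phase matrices for the shift grid (shared across particles)
    k <- freq_axis(n)
    phx <- exp(-2i * pi * outer(k, shift_grid$dx / px) / n)
    phy <- exp(-2i * pi * outer(k, shift_grid$dy / px) / n)
    Ph <- matrix(0i, n * n, ns)
    for (s in seq_len(ns))
      Ph[, s] <- as.vector(outer(phx[, s], phy[, s]))
    tPh <- t(Ph)
    pert <- sqrt(ang_grid$drot[col(matrix(0, ns, na))]^2 +
                 ang_grid$dtilt[col(matrix(0, ns, na))]^2 +
                 ang_grid$dpsi[col(matrix(0, ns, na))]^2 +
                 shift_grid$dx[row(matrix(0, ns, na))]^2 +
                 shift_grid$dy[row(matrix(0, ns, na))]^2)
    lex <- order(ang_grid$drot[col(matrix(0, ns, na))],
                 ang_grid$dtilt[col(matrix(0, ns, na))],
                 ang_grid$dpsi[col(matrix(0, ns, na))],
                 shift_grid$dx[row(matrix(0, ns, na))],
                 shift_grid$dy[row(matrix(0, ns, na))])
    lex_rank <- integer(ns * na); lex_rank[lex] <- seq_len(ns * na)
    for (i in seq_len(nrow(out))) {
      rots <- vapply(seq_len(na), function(a)
        euler_to_matrix(out$rot[i] + ang_grid$drot[a],
                        out$tilt[i] + ang_grid$dtilt[a],
                        out$psi[i] + ang_grid$dpsi[a]),
        matrix(0, 3, 3))
      slices <- cpp_slice_extract(fv, rots, n, 2)
      ctf <- ctf_from_row(out[i, ], n, px, voltage, cs, amplitude_contrast)
      refF <- matrix(slices, n * n, na) * as.vector(ctf)
      refF[(dc[2] - 1) * n + dc[1], ] <- 0i
      norm_ref <- sqrt(colSums(Mod(refF)^2))
      img <- stack$data[, , out$image_index[i]]
      if (!is.null(img_mask)) img <- (img - mean(img)) * img_mask
      fo <- fftc(img)
      fo[dc[1], dc[2]] <- 0i
      norm_obs <- sqrt(sum(Mod(fo)^2))
      base_ph <- as.vector(shift_phase(n, out$shift_x[i] / px,
                                       out$shift_y[i] / px))
      cross <- Conj(refF) * (as.vector(fo) * base_ph)
      scores <- Re(tPh %*% cross)              # ns x na
      scores <- scores / outer(rep(norm_obs, ns), norm_ref)
      best <- which(scores >= max(scores) - 1e-12 * abs(max(scores)))
      if (length(best) > 1)
        best <- best[order(pert[best], lex_rank[best])][1]
      a <- (best - 1) %/% ns + 1
      s <- (best - 1) %% ns + 1
      e <- matrix_to_euler(rots[, , a])
      out$rot[i] <- e[1]; out$tilt[i] <- e[2]; out$psi[i] <- e[3]
      out$shift_x[i] <- out$shift_x[i] + shift_grid$dx[s]
      out$shift_y[i] <- out$shift_y[i] + shift_grid$dy[s]
      out$ncc[i] <- scores[best[1]]
    }
  }
  out
}
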