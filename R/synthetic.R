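## Synthetic ground truth: C8 ring volumes built from a chiral Gaussian
## pseudo-atom motif, tilted-collection particle stacks with CTF and white
## Gaussian noise, and toy multi-chain atomic models with SSE annotations.
## Every generator is a pure function of (spec, seed).

default_motif <- function() {
  data.frame(
    x = c(0, 10, -6, 0, 7, -8),
    y = c(0, 2, 9, -9, 6, -5),
    z = c(0, 5, -4, 6, 10, -9),
    weight = c(1, 1, 1, 0.8, 0.9, 0.7),
    sigma = c(6, 5, 5, 5, 4, 4))
}

#' Ring specification
#'
#' @param n_sym cyclic symmetry order (8 for the nuclear-pore rings).
#' @param axis symmetry axis (default +z).
#' @param ring_radius subunit-center radius in Angstrom.
#' @param subunit_motif data.frame (x, y, z, weight, sigma) of Gaussian
#'   pseudo-atoms, coordinates relative to the subunit center in Angstrom.
#'   The default is a chiral 6-Gaussian arrangement so that all three Euler
#'   angles of a subunit are identifiable.
#' @return object of class `ring_spec`.
#' @export
ring_spec <- function(n_sym = 8, axis = c(0, 0, 1), ring_radius = 60,
                      subunit_motif = default_motif()) {
  stopifnot(n_sym >= 1, ring_radius > 0, nrow(subunit_motif) >= 1)
  structure(list(n_sym = as.integer(n_sym),
                 axis = axis / sqrt(sum(axis^2)),
                 ring_radius = ring_radius,
                 subunit_motif = subunit_motif),
            class = "ring_spec")
}

#' Collection specification
#'
#' Emulates a tilted-grid collection: discrete stage tilts with jitter,
#' uniform defocus in a range, white Gaussian noise at a target SNR.
#'
#' @param tilt_angles stage tilt angles in degrees.
#' @param tilt_weights sampling weights per tilt (uniform default; the
#'   per-tilt particle proportions of a real collection are unpublished).
#' @param tilt_jitter_sd per-particle tilt wobble, degrees.
#' @param defocus_range (min, max) defocus in Angstrom.
#' @param snr target signal-to-noise variance ratio inside a soft disc of
#'   radius 0.45 x box; `Inf` disables noise.
#' @param n_particles number of particles.
#' @param shift_sd per-axis Gaussian sd of the true shifts, Angstrom.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return object of class `collection_spec`.
#' @export
collection_spec <- function(tilt_angles = c(0, 30, 45, 55),
                            tilt_weights = NULL, tilt_jitter_sd = 2,
                            defocus_range = c(15000, 30000), snr = 1,
                            n_particles = 800, shift_sd = 2, seed = 1) {
  stopifnot(defocus_range[1] > 0, defocus_range[1] <= defocus_range[2],
            snr > 0, n_particles >= 1)
  if (is.null(tilt_weights)) tilt_weights <- rep(1, length(tilt_angles))
  structure(list(tilt_angles = tilt_angles, tilt_weights = tilt_weights,
                 tilt_jitter_sd = tilt_jitter_sd,
                 defocus_range = defocus_range, snr = snr,
                 n_particles = as.integer(n_particles),
                 shift_sd = shift_sd, seed = seed),
            class = "collection_spec")
}

## rotation taking +z onto a unit axis
z_to_axis <- function(axis) {
  z <- c(0, 0, 1)
  if (sum((axis - z)^2) < 1e-12) return(diag(3))
  if (sum((axis + z)^2) < 1e-12) return(rot_y(180))
  v <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  ang <- rad2deg(atan2(sqrt(sum(v^2)), sum(z * axis)))
  axis_rotation(v, ang)
}

ring_atom_positions <- function(spec) {
  M <- z_to_axis(spec$axis)
  c0 <- as.numeric(M %*% c(spec$ring_radius, 0, 0))
  p <- t(M %*% t(as.matrix(spec$subunit_motif[, c("x", "y", "z")])))
  lapply(seq_len(spec$n_sym) - 1L, function(k) {
    S <- axis_rotation(spec$axis, k * 360 / spec$n_sym)
    t(S %*% t(sweep(p, 2, c0, "+")))
  })
}

#' Build a toy ring volume with ground-truth model
#'
#' Density is the sum of the motif Gaussians replicated by the n_sym
#' rotations about the axis.  The returned model carries one chain per
#' subunit copy (`SUB0`, `SUB1`, ...) whose residues are the pseudo-atoms.
#'
#' @param spec [ring_spec()].
#' @param grid_n grid size (even).
#' @param pixel_size Angstrom per voxel.
#' @param seed kept for generator-API uniformity; the ring volume is
#'   deterministic given the spec.
#' @return list(volume = [volume_grid()], model = [atomic_model()]).
#' @export
make_toy_ring_volume <- function(spec, grid_n = 64, pixel_size = 3,
                                 seed = 1) {
  mo <- spec$subunit_motif
  extent <- max(sqrt(mo$x^2 + mo$y^2 + mo$z^2) + 3 * mo$sigma)
  need <- 2 * (spec$ring_radius + extent)
  if (need >= grid_n * pixel_size)
    stop("ring (diameter ", round(need), " A) exceeds the grid; need N >= ",
         ceiling(need / pixel_size) + 2)
  pos <- ring_atom_positions(spec)
  centers <- do.call(rbind, pos) / pixel_size
  w <- rep(mo$weight, spec$n_sym)
  s <- rep(mo$sigma, spec$n_sym) / pixel_size
  vol <- volume_grid(cpp_gaussian_splat(centers, w, s, grid_n), pixel_size)
  atoms <- do.call(rbind, lapply(seq_along(pos), function(i)
    data.frame(chain = sprintf("SUB%d", i - 1), resno = seq_len(nrow(mo)),
               resname = "GLY", atom = "CA", element = "C",
               x = pos[[i]][, 1], y = pos[[i]][, 2], z = pos[[i]][, 3],
               stringsAsFactors = FALSE)))
  chains <- data.frame(chain = sprintf("SUB%d", seq_along(pos) - 1),
                       entity = "subunit",
                       copy_label = sprintf("copy%d", seq_along(pos) - 1),
                       stringsAsFactors = FALSE)
  list(volume = vol, model = atomic_model(atoms, chains))
}

#' Build the single-subunit reference volume
#'
#' The motif of `spec` splatted at the grid center in the subunit reference
#' frame (the ring frame translated so the subunit-0 center is the origin).
#' With `neighborhood = TRUE` the other n_sym - 1 subunits are included at
#' their true relative positions (cropped to the grid): this is the
#' consistent reference for scoring extracted subparticle windows, which
#' also contain the neighboring density, and is what a subparticle
#' reconstruction converges to.
#'
#' @param spec [ring_spec()].
#' @param grid_n grid size.
#' @param pixel_size Angstrom per voxel.
#' @param neighborhood include neighboring subunits.
#' @return [volume_grid()].
#' @export
make_toy_subunit_volume <- function(spec, grid_n = 32, pixel_size = 3,
                                    neighborhood = FALSE) {
  M <- z_to_axis(spec$axis)
  mo <- spec$subunit_motif
  if (neighborhood) {
    c0 <- as.numeric(M %*% c(spec$ring_radius, 0, 0))
    pos <- ring_atom_positions(spec)
    p <- sweep(do.call(rbind, pos), 2, c0) / pixel_size
    w <- rep(mo$weight, spec$n_sym)
    s <- rep(mo$sigma, spec$n_sym) / pixel_size
  } else {
    p <- t(M %*% t(as.matrix(mo[, c("x", "y", "z")]))) / pixel_size
    w <- mo$weight
    s <- mo$sigma / pixel_size
  }
  volume_grid(cpp_gaussian_splat(p, w, s, grid_n), pixel_size)
}

#' Analytic projection of a Gaussian pseudo-atom ring
#'
#' Closed-form line integral of the ring density along the pose's +z axis:
#' each isotropic 3D Gaussian projects to a 2D Gaussian of weight
#' `w * sigma * sqrt(2*pi)` at the projected center.  Exact (no
#' interpolation), hence the reference projector for the synthetic world;
#' the Fourier central-slice route approximates it to within its trilinear
#' interpolation error.
#'
#' @param spec [ring_spec()].
#' @param pose 3x3 rotation matrix or (rot, tilt, psi) in degrees.
#' @param n image box size in pixels.
#' @param pixel_size Angstrom per pixel.
#' @param shift length-2 re-centering shift in Angstrom (the projected ring
#'   appears displaced by `-shift`).
#' @return n x n image in density * Angstrom units.
#' @export
project_ring_analytic <- function(spec, pose, n, pixel_size,
                                  shift = c(0, 0)) {
  R <- pose_matrix(pose)
  pos <- do.call(rbind, ring_atom_positions(spec))
  mo <- spec$subunit_motif
  w <- rep(mo$weight, spec$n_sym)
  s <- rep(mo$sigma, spec$n_sym)
  proj <- pos %*% t(R)                 # centers in the particle frame
  ax <- (seq_len(n) - 1 - n %/% 2) * pixel_size
  img <- matrix(0, n, n)
  for (j in seq_len(nrow(proj))) {
    mu <- proj[j, 1:2] - shift
    gx <- exp(-(ax - mu[1])^2 / (2 * s[j]^2))
    gy <- exp(-(ax - mu[2])^2 / (2 * s[j]^2))
    img <- img + (w[j] * s[j] * sqrt(2 * pi)) * outer(gx, gy)
  }
  img
}

#' Simulate a tilted-collection particle stack
#'
#' Each particle gets a uniform random in-plane orientation (rot, psi), a
#' stage tilt drawn from the collection's tilt angles plus jitter, Gaussian
#' shifts, a defocus uniform in the range, a CTF-filtered central-slice
#' projection of the volume, and white Gaussian noise scaled so that the
#' signal/noise variance ratio inside a soft disc of radius 0.45 x box
#' equals the requested SNR.
#'
#' @param volume [volume_grid()] ground-truth density.
#' @param cspec [collection_spec()].
#' @param ring optional [ring_spec()] describing `volume`; when supplied,
#'   projections are computed analytically (exact, no interpolation)
#'   instead of by Fourier central slice, so the simulated data are not an
#'   inverse crime of the reconstruction engine.
#' @param voltage,cs,amplitude_contrast global CTF parameters.
#' @return list(stack = [image_stack()], table = [particle_table()] with
#'   ground-truth poses, noise_sd and target snr columns).
#' @export
simulate_particles <- function(volume, cspec, ring = NULL, voltage = 300,
                               cs = 2.7, amplitude_contrast = 0.1) {
  if (cspec$snr <= 0) stop("snr must be > 0")
  n <- dim(volume$data)[1]
  px <- volume$pixel_size
  np <- cspec$n_particles
  set.seed(cspec$seed)
  rot <- stats::runif(np, -180, 180)
  psi <- stats::runif(np, -180, 180)
  tilt_base <- sample(seq_along(cspec$tilt_angles), np, replace = TRUE,
                      prob = cspec$tilt_weights)
  tilt <- cspec$tilt_angles[tilt_base] +
          stats::rnorm(np, 0, cspec$tilt_jitter_sd)
  tilt <- abs(tilt); tilt[tilt > 180] <- 360 - tilt[tilt > 180]
  sx <- stats::rnorm(np, 0, cspec$shift_sd)
  sy <- stats::rnorm(np, 0, cspec$shift_sd)
  dfu <- stats::runif(np, cspec$defocus_range[1], cspec$defocus_range[2])
  fv <- if (is.null(ring)) fftc_padded(volume$data, 2) else NULL
  disc <- soft_disc_mask(n, 0.45 * n)
  wsum <- sum(disc)
  imgs <- array(0, c(n, n, np))
  noise_sd <- numeric(np)
  for (i in seq_len(np)) {
    R <- euler_to_matrix(rot[i], tilt[i], psi[i])
    ctf <- evaluate_ctf(ctf_params(dfu[i], dfu[i], 0, voltage, cs,
                                   amplitude_contrast), n, px)
    if (is.null(ring)) {
      sl <- cpp_slice_extract(fv, array(R, c(3, 3, 1)), n, 2)[, , 1]
      sl <- sl * shift_phase(n, -sx[i] / px, -sy[i] / px)
    } else {
      sl <- fftc(project_ring_analytic(ring, R, n, px,
                                       shift = c(sx[i], sy[i])) / px)
    }
    sig <- Re(ifftc(sl * ctf)) * px
    mu <- sum(disc * sig) / wsum
    var_sig <- sum(disc * (sig - mu)^2) / wsum
    if (is.finite(cspec$snr)) {
      noise_sd[i] <- sqrt(var_sig / cspec$snr)
      sig <- sig + stats::rnorm(n * n, 0, noise_sd[i])
    }
    imgs[, , i] <- sig
  }
  tab <- particle_table(data.frame(
    image_name = "simulated.mrcs", image_index = seq_len(np),
    rot = rot, tilt = tilt, psi = psi, shift_x = sx, shift_y = sy,
    defocus_u = dfu, defocus_v = dfu, astig_angle = 0,
    pixel_size = px, group_id = tilt_base,
    noise_sd = noise_sd, snr = cspec$snr))
  list(stack = image_stack(imgs, px), table = tab)
}

ideal_helix <- function(n, origin = c(0, 0, 0), axis_offset = 0) {
  i <- seq_len(n)
  cbind(origin[1] + 1.5 * i,
        origin[2] + 2.3 * cos(deg2rad(100 * i + axis_offset)),
        origin[3] + 2.3 * sin(deg2rad(100 * i + axis_offset)))
}

toy_chain <- function(chain, helix_xyz, loop_xyz) {
  xyz <- rbind(helix_xyz, loop_xyz)
  data.frame(chain = chain, resno = seq_len(nrow(xyz)), resname = "ALA",
             atom = "CA", element = "C",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

## plain all-pairs CA contact scan (generation-time oracle, kept
## independent of the cell-list search in find_contacts)
brute_force_contacts <- function(model, cutoff = 8) {
  ca <- model_ca(model)
  out <- list()
  chs <- unique(ca$chain)
  for (i in seq_along(chs)) for (j in seq_along(chs)) {
    if (i >= j) next
    a <- ca[ca$chain == chs[i], ]
    b <- ca[ca$chain == chs[j], ]
    d <- sqrt(outer(a$x, b$x, `-`)^2 + outer(a$y, b$y, `-`)^2 +
              outer(a$z, b$z, `-`)^2)
    hit <- which(d <= cutoff, arr.ind = TRUE)
    if (nrow(hit))
      out[[length(out) + 1]] <- data.frame(
        chain_a = chs[i], resno_a = a$resno[hit[, 1]],
        chain_b = chs[j], resno_b = b$resno[hit[, 2]],
        distance = d[hit], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chain_a = character(), resno_a = integer(),
                      chain_b = character(), resno_b = integer(),
                      distance = numeric()))
  out <- do.call(rbind, out)
  out[order(out$chain_a, out$resno_a, out$chain_b, out$resno_b), ]
}

#' Generate paired toy atomic models
#'
#' Model A holds two entities x two copies (4 chains), each chain an ideal
#' alpha-helix (residues 1-30, SSE label "a1") followed by an extended loop
#' (residues 31-40, label "L1"); the loop of chain C is planted against the
#' helix of chain A (a helix-loop interface).  Model B is A under a random
#' rigid transform plus optional per-atom Gaussian jitter.  The contact
#' list is computed by a brute-force all-pairs scan at generation time.
#'
#' @param seed RNG seed.
#' @param jitter_sd per-coordinate Gaussian jitter on model B, Angstrom.
#' @param contact_cutoff CA-CA contact cutoff for the generated list.
#' @return list(model_a, model_b, true_rt = [transform_rt()], contacts).
#' @export
make_toy_models <- function(seed = 1, jitter_sd = 0, contact_cutoff = 8) {
  set.seed(seed)
  loop_line <- function(from, to, n = 10) {
    cbind(seq(from[1], to[1], length.out = n),
          seq(from[2], to[2], length.out = n),
          seq(from[3], to[3], length.out = n))
  }
  A <- toy_chain("A", ideal_helix(30),
                 loop_line(c(46, 3, 2), c(60, 12, 8)))
  C <- toy_chain("C", ideal_helix(30, origin = c(0, 40, 0), axis_offset = 60),
                 loop_line(c(22.5, 36, 0), c(22.5, 5.5, 0)))
  B <- toy_chain("B", ideal_helix(30, origin = c(0, 0, 60)),
                 loop_line(c(46, 3, 62), c(60, 12, 68)))
  D <- toy_chain("D", ideal_helix(30, origin = c(0, 40, 60), axis_offset = 60),
                 loop_line(c(22.5, 36, 60), c(22.5, 5.5, 60)))
  atoms <- rbind(A, C, B, D)
  chains <- data.frame(chain = c("A", "B", "C", "D"),
                       entity = c("NupA", "NupA", "NupB", "NupB"),
                       copy_label = c("inner", "outer", "inner", "outer"),
                       stringsAsFactors = FALSE)
  sse <- do.call(rbind, lapply(c("A", "B", "C", "D"), function(ch)
    data.frame(label = c("a1", "L1"), chain = ch,
               start = c(1, 31), end = c(30, 40), stringsAsFactors = FALSE)))
  model_a <- atomic_model(atoms, chains, sse)
  true_rt <- transform_rt(
    euler_to_matrix(stats::runif(1, -180, 180), stats::runif(1, 0, 180),
                    stats::runif(1, -180, 180)),
    stats::runif(3, -20, 20))
  model_b <- transform_model(model_a, true_rt)
  if (jitter_sd > 0) {
    nn <- nrow(model_b$atoms)
    model_b$atoms$x <- model_b$atoms$x + stats::rnorm(nn, 0, jitter_sd)
    model_b$atoms$y <- model_b$atoms$y + stats::rnorm(nn, 0, jitter_sd)
    model_b$atoms$z <- model_b$atoms$z + stats::rnorm(nn, 0, jitter_sd)
  }
  list(model_a = model_a, model_b = model_b, true_rt = true_rt,
       contacts = brute_force_contacts(model_a, contact_cutoff))
}
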