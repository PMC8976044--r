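test_that("CTF at zero frequency equals minus the amplitude contrast", {
  for (A in c(0, 0.07, 0.1, 1)) {
    ctf <- evaluate_ctf(ctf_params(2e4, amplitude_contrast = A), 32, 2)
    expect_equal(ctf[17, 17], -A, tolerance = 1e-14)
  }
})

test_that("round defocus gives a rotationally symmetric transfer", {
  c1 <- evaluate_ctf(ctf_params(2e4, 2e4, astig_angle = 0), 64, 1.5)
  c2 <- evaluate_ctf(ctf_params(2e4, 2e4, astig_angle = 61), 64, 1.5)
  expect_lt(max(abs(c1 - c2)), 1e-9)
  expect_lt(max(abs(c1 - t(c1))), 1e-9)
  ## astigmatic defocus is not
  c3 <- evaluate_ctf(ctf_params(2.2e4, 1.8e4, astig_angle = 30), 64, 1.5)
  expect_gt(max(abs(c3 - t(c3))), 1e-3)
})

test_that("first CTF zero matches an independent scalar root oracle", {
  z <- 20000; A <- 0.1; cs_mm <- 2.7; kv <- 300
  lam <- electron_wavelength(kv)
  ## oracle: transcribe the weak-phase formula and root-find on it
  gam <- function(f) pi * lam * z * f^2 - 0.5 * pi * (cs_mm * 1e7) * lam^3 * f^4
  ctf1d <- function(f) -(sqrt(1 - A^2) * sin(gam(f)) + A * cos(gam(f)))
  fs <- seq(1e-4, 0.05, by = 1e-5)
  v <- ctf1d(fs)
  i <- which(v[-1] * v[-length(v)] < 0)[1]
  oracle_zero <- stats::uniroot(ctf1d, c(fs[i], fs[i + 1]), tol = 1e-10)$root
  ## implementation: profile along the +kx axis of a fine grid
  n <- 512; px <- 2
  grid <- evaluate_ctf(ctf_params(z, z, voltage = kv, cs = cs_mm,
                                  amplitude_contrast = A), n, px)
  prof <- grid[(n / 2 + 1):n, n / 2 + 1]
  f_axis <- (0:(n / 2 - 1)) / (n * px)
  j <- which(prof[-1] * prof[-length(prof)] < 0)[1]
  impl_zero <- f_axis[j] + (f_axis[j + 1] - f_axis[j]) *
               prof[j] / (prof[j] - prof[j + 1])
  expect_lt(abs(impl_zero - oracle_zero), 1e-4)
})

test_that("identity-pose projection of a centered blob is radially symmetric", {
  g <- volume_grid(ringblock:::cpp_gaussian_splat(matrix(0, 1, 3), 1, 3, 32), 2)
  img <- project_volume(g, c(rot = 0, tilt = 0, psi = 0))
  expect_lt(max(abs(img - t(img))), 1e-12)
  ## mirror about the centered origin (0-based index N/2)
  idx <- 2:32
  expect_lt(max(abs(img[idx, idx] - img[rev(idx), rev(idx)])), 1e-10)
})

test_that("projection is equivariant under volume rotation", {
  ## smooth, compact blob pair: keeps both the real-space resampling error
  ## and the Fourier wraparound negligible
  g <- volume_grid(ringblock:::cpp_gaussian_splat(
    matrix(c(2, -1, 1.5, -2.5, 1.5, -1), 2, 3, byrow = TRUE),
    c(1, 0.7), c(4, 4.5), 48), 2)
  R0 <- euler_to_matrix(15, 30, -20)
  R1 <- euler_to_matrix(-50, 60, 10)
  vrot <- volume_grid(ringblock:::cpp_resample(g$data, R0, c(0, 0, 0), 48), 2)
  p_a <- project_volume(vrot, R1)
  p_b <- project_volume(g, R1 %*% R0)
  expect_lt(max(abs(p_a - p_b)) / max(abs(p_b)), 0.01)
})

test_that("projection conserves mass", {
  vol <- fx_ring64()$volume
  for (pose in list(c(rot = 0, tilt = 0, psi = 0),
                    c(rot = 33, tilt = 55, psi = -110))) {
    img <- project_volume(vol, pose)
    expect_lt(abs(sum(img) - sum(vol$data) * vol$pixel_size) /
              (sum(vol$data) * vol$pixel_size), 0.005)
  }
})

test_that("both projection routes agree on a smooth volume", {
  g <- volume_grid(ringblock:::cpp_gaussian_splat(
    matrix(c(2, -1, 1.5), 1, 3), 1, 3, 32), 2)
  pose <- c(rot = 25, tilt = 40, psi = 70)
  pf <- project_volume(g, pose, shift = c(3, -2))
  pr <- project_volume(g, pose, shift = c(3, -2), method = "real")
  expect_lt(max(abs(pf - pr)) / max(abs(pf)), 0.02)
})

test_that("single identity-pose particle reconstructs its central plane", {
  vol <- fx_ring64()$volume
  img <- project_volume(vol, c(rot = 0, tilt = 0, psi = 0))
  tab <- particle_table(data.frame(
    rot = 0, tilt = 0, psi = 0, shift_x = 0, shift_y = 0,
    defocus_u = 2e4, defocus_v = 2e4, pixel_size = 3))
  rec <- reconstruct(image_stack(array(img, c(64, 64, 1)), 3), tab,
                     ctf = FALSE, eps_frac = 1e-12)
  ## a single central slice back-transforms to a z-constant volume whose
  ## every plane is the input image scaled by 1 / (N * pixel)
  expect_lt(max(abs(rec$data[, , 10] - rec$data[, , 40])), 1e-12)
  expect_lt(max(abs(rec$data[, , 33] * 64 * 3 - img)) / max(abs(img)), 1e-4)
})

test_that("noise-free multi-view reconstruction correlates with the truth", {
  vol <- fx_ring64()$volume
  set.seed(21)
  np <- 500
  tab <- particle_table(data.frame(
    rot = runif(np, -180, 180),
    tilt = acos(runif(np, -1, 1)) * 180 / pi,
    psi = runif(np, -180, 180), shift_x = 0, shift_y = 0,
    defocus_u = 2e4, defocus_v = 2e4, pixel_size = 3))
  st <- project_stack(vol, tab)
  rec <- reconstruct(st, tab, ctf = FALSE)
  fsc <- compute_fsc(rec, vol)
  upto <- which(fsc$freq <= 0.8 / (2 * vol$pixel_size))
  expect_true(all(fsc$fsc[upto] > 0.95))
})

test_that("reconstruction demands enough particles per half-set", {
  sim <- fx_sim(n = 3, seed = 5)
  expect_error(reconstruct(sim$stack, sim$table, half_sets = TRUE),
               "half-set")
})

test_that("FSC of a volume with itself is 1 in every shell", {
  vol <- fx_ring64()$volume
  fsc <- compute_fsc(vol, vol)
  expect_true(all(abs(fsc$fsc - 1) < 1e-12))
  expect_equal(resolution_at(fsc), 2 * vol$pixel_size)
})

test_that("FSC is symmetric and scale invariant; size mismatch errors", {
  set.seed(8)
  a <- volume_grid(array(rnorm(32^3), c(32, 32, 32)), 2)
  b <- volume_grid(array(rnorm(32^3), c(32, 32, 32)), 2)
  f_ab <- compute_fsc(a, b)
  f_ba <- compute_fsc(b, a)
  expect_equal(f_ab$fsc, f_ba$fsc, tolerance = 1e-12)
  b5 <- volume_grid(5 * b$data, 2)
  expect_equal(compute_fsc(a, b5)$fsc, f_ab$fsc, tolerance = 1e-12)
  small <- volume_grid(array(0, c(16, 16, 16)), 2)
  expect_error(compute_fsc(a, small), "different grid")
})

test_that("white-noise FSC stays within the null band", {
  set.seed(9)
  a <- volume_grid(array(rnorm(48^3), c(48, 48, 48)), 2)
  b <- volume_grid(array(rnorm(48^3), c(48, 48, 48)), 2)
  fsc <- compute_fsc(a, b)
  frac_in_band <- mean(abs(fsc$fsc) < 3 / sqrt(fsc$n_voxels))
  expect_gte(frac_in_band, 0.9)
})

test_that("reported resolution never beats the Nyquist floor", {
  vol <- fx_ring64()$volume
  curves <- list(compute_fsc(vol, vol))
  sim <- fx_sim(n = 40, seed = 3)
  halves <- reconstruct(sim$stack, symmetry_expand(sim$table, 8),
                        half_sets = TRUE)
  curves[[2]] <- compute_fsc(halves[[1]], halves[[2]])
  for (cv in curves)
    expect_gte(resolution_at(cv), 2 * vol$pixel_size)
})

test_that("projection and backprojection are adjoint within 1%", {
  g <- volume_grid(ringblock:::cpp_gaussian_splat(
    matrix(c(3, -4, 5, -6, 2, -8), 2, 3, byrow = TRUE),
    c(1, 0.8), c(5, 4), 32), 2)
  set.seed(1)
  m <- matrix(0, 32, 32)
  m[10:20, 12:25] <- rnorm(11 * 14)
  m <- Re(ringblock:::ifftc(ringblock:::fftc(m) *
                            ringblock:::soft_disc_mask(32, 10)))
  R <- euler_to_matrix(33, 70, -15)
  ## oversample = 1: the native extraction/insertion pair is exactly adjoint
  lhs <- sum(project_volume(g, R, oversample = 1) * m)
  rhs <- sum(g$data * backproject(m, R, 2)$data)
  expect_lt(abs(lhs - rhs) / abs(lhs), 0.01)
})

test_that("doubling particle count never worsens reported resolution", {
  for (seed in 1:5) {
    sim <- fx_sim(n = 120, snr = 1, seed = 100 + seed)
    half_res <- function(tab) {
      halves <- reconstruct(sim$stack, tab, half_sets = TRUE)
      resolution_at(compute_fsc(halves[[1]], halves[[2]],
                                soft_sphere_mask(64, 3, 86, 12)))
    }
    r60 <- half_res(sim$table[1:60, ])
    r120 <- half_res(sim$table)
    expect_lte(r120, r60 + 1e-9)
  }
})
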