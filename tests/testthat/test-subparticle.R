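test_that("symmetry expansion: degenerate and identity cases", {
  sim <- fx_sim(n = 5, seed = 3)
  expect_identical(symmetry_expand(sim$table, 1), sim$table)
  ex <- symmetry_expand(sim$table, 8)
  expect_equal(nrow(ex), 40)
  expect_equal(ex$subunit_index, rep(0:7, 5))
  ## shifts and defocus copied untouched
  expect_equal(ex$defocus_u, rep(sim$table$defocus_u, each = 8))
  expect_equal(ex$shift_x, rep(sim$table$shift_x, each = 8))

  idt <- particle_table(data.frame(
    rot = 0, tilt = 0, psi = 0, shift_x = 0, shift_y = 0,
    defocus_u = 2e4, defocus_v = 2e4, pixel_size = 3))
  e8 <- symmetry_expand(idt, 8)
  expect_equal(sort(normalize_angle(e8$rot + e8$psi)),
               c(-135, -90, -45, 0, 45, 90, 135, 180))
  expect_true(all(e8$tilt == 0))
})

test_that("expanded poses project the ring identically (analytic oracle)", {
  rs <- fx_ring_spec()
  sim <- fx_sim(n = 2, seed = 3)
  ex <- symmetry_expand(sim$table, 8)
  p0 <- project_ring_analytic(rs, c(rot = ex$rot[1], tilt = ex$tilt[1],
                                    psi = ex$psi[1]), 64, 3)
  for (k in c(2, 5, 8)) {
    pk <- project_ring_analytic(rs, c(rot = ex$rot[k], tilt = ex$tilt[k],
                                      psi = ex$psi[k]), 64, 3)
    expect_lt(max(abs(pk - p0)) / max(abs(p0)), 0.01)
  }
})

test_that("re-centering: trivial frames leave records unchanged", {
  tab <- particle_table(data.frame(
    rot = 0, tilt = 0, psi = 0, shift_x = 1.5, shift_y = -2,
    defocus_u = 2e4, defocus_v = 2e4, pixel_size = 3, subunit_index = 0L))
  rc0 <- recenter_subparticles(tab, subunit_frame(c(0, 0, 0), 1,
                                                  check = FALSE), 64)
  expect_equal(rc0$shift_x, 1.5)
  expect_equal(rc0$defocus_u, 2e4)
  ## purely axial center: defocus moves by exactly c, shifts untouched
  rcz <- recenter_subparticles(tab, subunit_frame(c(0, 0, 50), 1,
                                                  check = FALSE), 64)
  expect_equal(rcz$defocus_u, 2e4 + 50)
  expect_equal(rcz$defocus_v, 2e4 + 50)
  expect_equal(rcz$shift_x, 1.5)
  expect_equal(rcz$offset_x, 0L)
})

test_that("re-centering splits shifts into integer offsets plus fractions", {
  tab <- particle_table(data.frame(
    rot = 0, tilt = 0, psi = 0, shift_x = 0, shift_y = 0,
    defocus_u = 2e4, defocus_v = 2e4, pixel_size = 3, subunit_index = 0L))
  rc <- recenter_subparticles(tab, subunit_frame(c(60, 0, 0), 8), 64)
  ## q = (60, 0, 0): new shift -60 A = -20 px exactly
  expect_equal(rc$offset_x, -20L)
  expect_equal(rc$shift_x, 0)
  expect_equal(rc$defocus_u, 2e4)
  ## fractional component survives in the shift fields
  tab2 <- particle_table(data.frame(
    rot = 0, tilt = 0, psi = 0, shift_x = 1.2, shift_y = 0,
    defocus_u = 2e4, defocus_v = 2e4, pixel_size = 3, subunit_index = 0L))
  rc2 <- recenter_subparticles(tab2, subunit_frame(c(60, 0, 0), 8), 64)
  expect_equal(rc2$offset_x * 3 + rc2$shift_x, 1.2 - 60, tolerance = 1e-12)
  expect_lte(abs(rc2$shift_x), 1.5)
})

test_that("subparticles projecting outside the box are excluded and counted", {
  tab <- particle_table(data.frame(
    rot = 0, tilt = 0, psi = 0, shift_x = 0, shift_y = 0,
    defocus_u = 2e4, defocus_v = 2e4, pixel_size = 3, subunit_index = 0L))
  expect_message(
    rc <- recenter_subparticles(tab, subunit_frame(c(150, 0, 0), 8), 64),
    "excluded")
  expect_equal(nrow(rc), 0)
  expect_equal(attr(rc, "n_excluded"), 1L)
})

test_that("defocus bookkeeping matches the simulator's ground truth", {
  ## independent oracle: rotate the subunit center with the true pose and
  ## add its z component to the micrograph defocus
  sim <- fx_sim(n = 50, seed = 31)
  frame <- subunit_frame(c(60, 0, 0), 8)
  ex <- symmetry_expand(sim$table, 8)
  rc <- recenter_subparticles(ex, frame, 64)
  truth <- vapply(seq_len(nrow(ex)), function(i) {
    R <- euler_to_matrix(ex$rot[i], ex$tilt[i], ex$psi[i])
    ex$defocus_u[i] + (R %*% c(60, 0, 0))[3]
  }, 0)
  expect_lt(max(abs(rc$defocus_u - truth)), 1e-9)
})

test_that("extraction: identity crop, blob centroid, mean padding", {
  sim <- fx_sim(n = 2, seed = 3)
  tab <- sim$table
  tab$offset_x <- 0L; tab$offset_y <- 0L
  ex <- extract_subparticles(sim$stack, tab, 64)
  expect_equal(ex$stack$data, sim$stack$data)
  expect_error(extract_subparticles(sim$stack, tab, 128), "exceeds")
  expect_error(extract_subparticles(sim$stack, sim$table, 32),
               "recenter_subparticles")

  ## known blob at q: centroid lands within 1 px of the window center
  n <- 64; px <- 3
  blob <- ringblock:::cpp_gaussian_splat(matrix(c(30, -21, 0) / px, 1, 3),
                                         1, 2, n)
  img <- apply(blob, c(1, 2), sum)
  tb <- particle_table(data.frame(
    rot = 0, tilt = 0, psi = 0, shift_x = 0, shift_y = 0,
    defocus_u = 2e4, defocus_v = 2e4, pixel_size = px, subunit_index = 0L))
  rc <- recenter_subparticles(tb, subunit_frame(c(30, -21, 0), 8), n)
  exb <- extract_subparticles(image_stack(array(img, c(n, n, 1)), px), rc, 16)
  win <- exb$stack$data[, , 1]
  cx <- sum(row(win) * win) / sum(win)
  cy <- sum(col(win) * win) / sum(win)
  expect_lt(abs(cx - 9), 1)   # 0-based center 8 -> 1-based 9
  expect_lt(abs(cy - 9), 1)

  ## edge window: padded with the source mean
  tb2 <- tb
  tb2$offset_x <- -28L; tb2$offset_y <- 0L
  expect_message(exe <- extract_subparticles(
    image_stack(array(img, c(n, n, 1)), px), tb2, 16), "padded")
  expect_equal(attr(exe$stack, "n_padded"), 1L)
  expect_lt(abs(exe$stack$data[16, 1, 1] - mean(img)), 1e-6)
})

test_that("local refinement returns the exact truth when it is in the grid", {
  ## engine-consistent (slice-projected) noise-free stack
  sim <- fx_sim(n = 5, snr = Inf, seed = 5, analytic = FALSE)
  out <- local_refine(sim$stack, fx_ring64()$volume, sim$table, 4, 2, 3, 1.5)
  expect_lt(max(abs(out$rot - sim$table$rot)), 1e-9)
  expect_lt(max(abs(out$tilt - sim$table$tilt)), 1e-9)
  expect_lt(max(abs(out$psi - sim$table$psi)), 1e-9)
  expect_equal(out$shift_x, sim$table$shift_x)
  expect_equal(out$shift_y, sim$table$shift_y)
})

test_that("local refinement recovers perturbed poses at SNR 1", {
  ## 60-particle pilot of the acceptance A1 world (800 particles there)
  n <- 60
  sim <- fx_sim(n = n, snr = 1, seed = 6)
  set.seed(7)
  pert <- sim$table
  pert$rot <- normalize_angle(pert$rot + runif(n, -4, 4))
  pert$tilt <- pmin(180, abs(pert$tilt + runif(n, -4, 4)))
  pert$psi <- normalize_angle(pert$psi + runif(n, -4, 4))
  pert$shift_x <- pert$shift_x + runif(n, -3, 3)
  pert$shift_y <- pert$shift_y + runif(n, -3, 3)
  out <- local_refine(sim$stack, fx_ring64()$volume, pert, 4, 2, 3, 1.5)
  ang <- table_angle_errors(out, sim$table)
  shf <- pmax(abs(out$shift_x - sim$table$shift_x),
              abs(out$shift_y - sim$table$shift_y))
  expect_gte(mean(ang <= sqrt(3) * 2 & shf <= 1.5), 0.95)
})

test_that("local refinement validates its search grid", {
  sim <- fx_sim(n = 2, seed = 3)
  expect_error(local_refine(sim$stack, fx_ring64()$volume, sim$table,
                            -1, 2, 3, 1.5))
  expect_error(local_refine(sim$stack, fx_ring64()$volume, sim$table,
                            4, 0, 3, 1.5))
  small_ref <- make_toy_subunit_volume(fx_ring_spec(), 32, 3)
  expect_error(local_refine(sim$stack, small_ref, sim$table, 4, 2, 3, 1.5),
               "box")
  wrong_px <- volume_grid(fx_ring64()$volume$data, 2)
  expect_error(local_refine(sim$stack, wrong_px, sim$table, 4, 2, 3, 1.5),
               "pixel")
})
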