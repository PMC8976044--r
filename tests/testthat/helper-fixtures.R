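# Shared fixtures and independent oracles.  Heavy objects are built once
# per session and cached.

.fx <- new.env(parent = emptyenv())

fx_ring_spec <- function() ring_spec()

fx_ring64 <- function() {
  if (is.null(.fx$ring64))
    .fx$ring64 <- make_toy_ring_volume(fx_ring_spec(), 64, 3)
  .fx$ring64
}

fx_sim <- function(n = 40, snr = 1, seed = 3, analytic = TRUE) {
  key <- sprintf("sim_%d_%s_%d_%d", n, format(snr), seed, analytic)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- simulate_particles(
      fx_ring64()$volume,
      collection_spec(n_particles = n, snr = snr, seed = seed),
      ring = if (analytic) fx_ring_spec() else NULL)
  .fx[[key]]
}

# geodesic angle (degrees) between two poses given as Euler triples
pose_angle_error <- function(a, b) {
  Ra <- euler_to_matrix(a[1], a[2], a[3])
  Rb <- euler_to_matrix(b[1], b[2], b[3])
  tr <- sum(diag(t(Ra) %*% Rb))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

table_angle_errors <- function(tab_a, tab_b) {
  vapply(seq_len(nrow(tab_a)), function(i)
    pose_angle_error(c(tab_a$rot[i], tab_a$tilt[i], tab_a$psi[i]),
                     c(tab_b$rot[i], tab_b$tilt[i], tab_b$psi[i])), 0)
}

# independent all-pairs contact oracle (deliberately naive; the package
# uses a cell list)
oracle_contacts <- function(model, chains_a, chains_b, cutoff, mode) {
  at <- model$atoms
  if (mode == "ca") at <- at[at$atom == "CA", ]
  A <- at[at$chain %in% chains_a, ]
  B <- at[at$chain %in% chains_b, ]
  out <- NULL
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 +
              (A$z[i] - B$z[j])^2)
    if (d <= cutoff)
      out <- rbind(out, data.frame(chain_a = A$chain[i], resno_a = A$resno[i],
                                   chain_b = B$chain[j], resno_b = B$resno[j],
                                   distance = d))
  }
  if (is.null(out)) return(out)
  # min distance per residue pair
  key <- paste(out$chain_a, out$resno_a, out$chain_b, out$resno_b)
  out <- out[order(key, out$distance), ]
  out <- out[!duplicated(paste(out$chain_a, out$resno_a, out$chain_b,
                               out$resno_b)), ]
  out[order(out$chain_a, out$resno_a, out$chain_b, out$resno_b), ]
}

# random point-cloud model with two chains for contact property tests
random_two_chain_model <- function(seed, n = 25, spread = 30) {
  set.seed(seed)
  mk <- function(ch) data.frame(
    chain = ch, resno = seq_len(n), resname = "GLY", atom = "CA",
    element = "C",
    x = runif(n, -spread, spread), y = runif(n, -spread, spread),
    z = runif(n, -spread, spread), stringsAsFactors = FALSE)
  atomic_model(rbind(mk("A"), mk("B")))
}

# minimal synthetic chain with CA atoms at given residue numbers/coords
line_chain_model <- function(resnos, coords, chain = "A", entity = "NupX") {
  atomic_model(
    data.frame(chain = chain, resno = resnos, resname = "ALA", atom = "CA",
               element = "C", x = coords[, 1], y = coords[, 2],
               z = coords[, 3], stringsAsFactors = FALSE),
    data.frame(chain = chain, entity = entity, copy_label = NA_character_,
               stringsAsFactors = FALSE))
}
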