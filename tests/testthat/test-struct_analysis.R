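test_that("superposing a model onto itself gives zero and identity", {
  tm <- make_toy_models(seed = 5)
  s <- superpose(tm$model_a, tm$model_a)
  expect_lt(s$rmsd, 1e-12)
  expect_lt(max(abs(s$transform$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(s$transform$translation)), 1e-12)
})

test_that("a 30-degree z-rotation is recovered to machine precision", {
  tm <- make_toy_models(seed = 5)
  rot <- transform_model(tm$model_a,
                         transform_rt(axis_rotation(c(0, 0, 1), 30)))
  s <- superpose(tm$model_a, rot)
  expect_lt(s$rmsd, 1e-9)
  ang <- acos((sum(diag(s$transform$rotation)) - 1) / 2) * 180 / pi
  expect_equal(ang, 30, tolerance = 1e-9)
})

test_that("reported RMSD equals the brute-force residual of the transform", {
  set.seed(31)
  for (rep in 1:5) {
    tm <- make_toy_models(seed = 40 + rep, jitter_sd = 0.8)
    s <- superpose(tm$model_a, tm$model_b)
    X <- as.matrix(model_ca(tm$model_a)[, c("x", "y", "z")])
    Y <- as.matrix(model_ca(tm$model_b)[, c("x", "y", "z")])
    fitted <- apply_rt(s$transform, X)
    expect_equal(s$rmsd, sqrt(mean(rowSums((fitted - Y)^2))),
                 tolerance = 1e-9)
    ## and no rigid transform does better (probe a few perturbations)
    for (k in 1:3) {
      pert <- compose_rt(transform_rt(
        euler_to_matrix(rnorm(1, 0, 0.5), abs(rnorm(1, 0, 0.5)),
                        rnorm(1, 0, 0.5)), rnorm(3, 0, 0.3)), s$transform)
      worse <- sqrt(mean(rowSums((apply_rt(pert, X) - Y)^2)))
      expect_gte(worse, s$rmsd - 1e-9)
    }
  }
})

test_that("correspondence policies select the intended pairs", {
  tm <- make_toy_models(seed = 5)
  ## chain ids differ but (entity, copy, resno) match
  renamed <- tm$model_b
  map <- c(A = "W", B = "X", C = "Y", D = "Z")
  renamed$atoms$chain <- unname(map[renamed$atoms$chain])
  renamed$chains$chain <- unname(map[renamed$chains$chain])
  s <- superpose(tm$model_a, renamed, policy = "entity_copy_resno")
  expect_equal(s$n_aligned, 160)
  expect_lt(s$rmsd, 1e-9)
  ## chain policy now finds nothing
  expect_error(superpose(tm$model_a, renamed, policy = "chain_resno"),
               "at least 3")
  ## explicit pairs
  pairs <- data.frame(chain_a = "A", resno_a = 1:30,
                      chain_b = "W", resno_b = 1:30)
  s2 <- superpose(tm$model_a, renamed, policy = "pairs", pairs = pairs)
  expect_equal(s2$n_aligned, 30)
  expect_error(superpose(tm$model_a, renamed, policy = "pairs"), "pair list")
})

test_that("cell-list contacts equal the all-pairs oracle on random models", {
  for (seed in 1:50) {
    m <- random_two_chain_model(seed)
    cutoff <- runif(1, 4, 9)
    found <- find_contacts(m, "A", "B", cutoff = cutoff, mode = "ca")
    want <- oracle_contacts(m, "A", "B", cutoff, "ca")
    if (is.null(want)) {
      expect_equal(nrow(found), 0)
    } else {
      kf <- paste(found$chain_a, found$resno_a, found$chain_b, found$resno_b)
      kw <- paste(want$chain_a, want$resno_a, want$chain_b, want$resno_b)
      expect_identical(sort(kf), sort(kw))
      expect_equal(found$distance, want$distance[match(kf, kw)],
                   tolerance = 1e-12)
    }
  }
})

test_that("contacts: disjointness, unknown chains, separated chains", {
  tm <- make_toy_models(seed = 3)
  expect_error(find_contacts(tm$model_a, c("A", "B"), c("B", "C")),
               "disjoint")
  expect_error(find_contacts(tm$model_a, "A", "Q"), "unknown chain")
  ## chains A and D sit 60 A apart in z: no all-atom contacts
  expect_equal(nrow(find_contacts(tm$model_a, "A", "D")), 0)
})

test_that("planted interface shows up as a helix-loop SSE pairing", {
  tm <- make_toy_models(seed = 3)
  ct <- find_contacts(tm$model_a, "A", "C", mode = "ca")
  expect_gt(nrow(ct), 0)
  expect_true(any(ct$sse_a == "a1" & ct$sse_b == "L1"))
  ## grouping by SSE reproduces the planted geometry: every contact of the
  ## A helix lands in the C loop
  helix_rows <- ct[ct$sse_a == "a1", ]
  expect_true(all(helix_rows$sse_b == "L1"))
})

test_that("linker reachability reproduces the bridging arithmetic", {
  ## anchors 28 residues apart at 74 A: reachable (max span 106.4 A)
  m74 <- line_chain_model(c(152, 180),
                          rbind(c(0, 0, 0), c(74, 0, 0)))
  r <- linker_reachability(m74, list("A", 152), list("A", 180))
  expect_equal(r$n_steps, 28)
  expect_equal(r$max_span, 28 * 3.8)
  expect_equal(r$distance, 74)
  expect_true(r$feasible)
  ## the same span cannot bridge 300 A
  m300 <- line_chain_model(c(152, 180),
                           rbind(c(0, 0, 0), c(300, 0, 0)))
  expect_false(linker_reachability(m300, list("A", 152),
                                   list("A", 180))$feasible)
  ## coincident anchors are trivially feasible
  m0 <- line_chain_model(c(10, 20), rbind(c(5, 5, 5), c(5, 5, 5)))
  r0 <- linker_reachability(m0, list("A", 10), list("A", 20))
  expect_equal(r0$distance, 0)
  expect_true(r0$feasible)
})

test_that("feasibility is monotone in the linker length", {
  set.seed(71)
  for (i in 1:20) {
    d <- runif(1, 0, 200)
    m <- line_chain_model(c(1, 100), rbind(c(0, 0, 0), c(d, 0, 0)))
    feas <- vapply(seq(5, 95, by = 10), function(gap) {
      mg <- line_chain_model(c(1, 1 + gap), rbind(c(0, 0, 0), c(d, 0, 0)))
      linker_reachability(mg, list("A", 1), list("A", 1 + gap))$feasible
    }, TRUE)
    expect_true(all(diff(as.integer(feas)) >= 0))
  }
})

test_that("cross-entity anchors need an explicit override", {
  a <- line_chain_model(c(1, 10), rbind(c(0, 0, 0), c(30, 0, 0)),
                        chain = "A", entity = "NupA")
  b <- line_chain_model(c(1, 10), rbind(c(5, 0, 0), c(40, 0, 0)),
                        chain = "B", entity = "NupB")
  m <- atomic_model(rbind(a$atoms, b$atoms),
                    rbind(a$chains, b$chains))
  expect_error(linker_reachability(m, list("A", 10), list("B", 1)),
               "different entities")
  r <- linker_reachability(m, list("A", 10), list("B", 1),
                           allow_cross_entity = TRUE)
  expect_equal(r$distance, 25)
  expect_error(linker_reachability(m, list("A", 99), list("A", 1)),
               "not found")
})

test_that("census counts chains, entities, residues and mass", {
  tm <- make_toy_models(seed = 3)
  cen <- model_census(tm$model_a)
  expect_equal(cen$n_chains, 4)
  expect_equal(cen$n_entities, 2)
  expect_equal(cen$n_residues, 160)
  expect_equal(cen$mass_da, 160 * 110)
  ## additive over chain subsets
  part <- function(chs) {
    sub <- tm$model_a
    sub$atoms <- sub$atoms[sub$atoms$chain %in% chs, ]
    sub$chains <- sub$chains[sub$chains$chain %in% chs, ]
    model_census(sub)$n_residues
  }
  expect_equal(part(c("A", "B")) + part(c("C", "D")), cen$n_residues)
  ## exclusion list removes whole entities
  cen2 <- model_census(tm$model_a, exclude_entities = "NupB")
  expect_equal(cen2$n_chains, 2)
  expect_equal(cen2$n_entities, 1)
  ## invariant under atom reordering
  shuf <- tm$model_a
  shuf$atoms <- shuf$atoms[rev(seq_len(nrow(shuf$atoms))), ]
  expect_equal(model_census(shuf)$n_residues, cen$n_residues)
})
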