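## End-to-end toy study: simulate ring data with imperfect whole-ring
## alignment, whole-ring C8 reconstruction, layered-mask focusing,
## subparticle extraction + confined refinement, FSC reporting, composite
## assembly, and structural analyses -- all from one config with explicit
## seeds.  Every stage writes its artifacts into the run directory and the
## final JSON report carries a manifest with md5 hashes.

#' Default pipeline configuration
#'
#' The stated toy world: a C8 ring of radius 60 A on a 64^3 grid at
#' 3 A/voxel, 800 particles at SNR 1 from a 0/30/45/55-degree tilt
#' collection with defocus 1.5-3.0 um, whole-ring alignment errors of 3
#' degrees / 1 A (the imperfection that block-based refinement recovers),
#' subparticle box 32, confined search of +/-4 degrees in 2-degree steps
#' and +/-3 A in 1.5 A steps.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    grid_n = 64, pixel_size = 3,
    ring = list(n_sym = 8, ring_radius = 60),
    collection = list(n_particles = 800, snr = 1,
                      tilt_angles = c(0, 30, 45, 55), tilt_jitter_sd = 2,
                      defocus_range = c(15000, 30000), shift_sd = 2),
    alignment_error = list(angle_sd = 3, shift_sd = 1),
    layer = list(z_start = -30, z_end = 30, transition_width = 15),
    subparticle = list(box = 32),
    refine = list(angular_range = 4, angular_step = 2,
                  shift_range = 3, shift_step = 1.5, rounds = 1,
                  mask_radius = 30),
    fsc_threshold = 0.143)
}

log_line <- function(state, stage, msg) {
  line <- sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(state$log)) cat(line, "\n", file = state$log, append = TRUE)
}

#' Run the toy block-based reconstruction pipeline
#'
#' Stages: simulate -> whole-ring C8 reconstruction -> layered-mask focus
#' -> subparticle expand/recenter/extract -> confined local refinement ->
#' half-set reconstructions and FSC before/after -> composite assembly ->
#' structural analyses.  Deterministic given the config seeds; artifacts
#' land in `out_dir` and the returned report is also written as JSON.
#'
#' @param config configuration list (see [default_pipeline_config()]) or a
#'   path to a YAML file with the same structure.
#' @param out_dir output directory (created if needed).
#' @return report list (invisibly identical to report.json).
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("ringblock_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_pipeline_config()
  config <- utils::modifyList(base, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list(log = file.path(out_dir, "run.log"))
  report <- list(config = config)
  stage <- function(name, expr) {
    log_line(state, name, "start")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  n <- config$grid_n; px <- config$pixel_size
  nsym <- config$ring$n_sym

  ## ---- simulate ----
  sim <- stage("simulate", {
    rspec <- ring_spec(n_sym = nsym, ring_radius = config$ring$ring_radius)
    ring <- make_toy_ring_volume(rspec, n, px)
    cs <- collection_spec(
      tilt_angles = config$collection$tilt_angles,
      tilt_jitter_sd = config$collection$tilt_jitter_sd,
      defocus_range = config$collection$defocus_range,
      snr = config$collection$snr,
      n_particles = config$collection$n_particles,
      shift_sd = config$collection$shift_sd,
      seed = config$seed)
    s <- simulate_particles(ring$volume, cs, ring = rspec)
    write_volume(ring$volume, file.path(out_dir, "ring_truth.mrc"))
    write_stack(s$stack, file.path(out_dir, "particles.mrc"))
    write_particle_table(s$table, file.path(out_dir, "particles_truth.star"))
    list(rspec = rspec, ring = ring, stack = s$stack, truth = s$table)
  })

  ## ---- alignment error: the imperfect whole-ring consensus table ----
  observed <- stage("perturb", {
    set.seed(config$seed + 1)
    tab <- sim$truth
    np <- nrow(tab)
    ae <- config$alignment_error
    tab$rot <- normalize_angle(tab$rot + stats::rnorm(np, 0, ae$angle_sd))
    tab$tilt <- pmin(180, abs(tab$tilt + stats::rnorm(np, 0, ae$angle_sd)))
    tab$psi <- normalize_angle(tab$psi + stats::rnorm(np, 0, ae$angle_sd))
    tab$shift_x <- tab$shift_x + stats::rnorm(np, 0, ae$shift_sd)
    tab$shift_y <- tab$shift_y + stats::rnorm(np, 0, ae$shift_sd)
    write_particle_table(tab, file.path(out_dir, "particles_observed.star"))
    tab
  })

  ## ---- whole-ring reconstruction (C8 via symmetry expansion) ----
  ring_res <- stage("reconstruct", {
    exp_tab <- symmetry_expand(observed, nsym)
    halves <- reconstruct(sim$stack, exp_tab, half_sets = TRUE)
    mask <- soft_sphere_mask(n, px, 0.45 * n * px, 4 * px)
    curve <- compute_fsc(halves[[1]], halves[[2]], mask)
    res <- resolution_at(curve, config$fsc_threshold)
    full <- reconstruct(sim$stack, exp_tab)
    write_volume(full, file.path(out_dir, "ring_recon.mrc"))
    write_fsc_tsv(curve, file.path(out_dir, "fsc_ring.tsv"))
    log_line(state, "reconstruct",
             sprintf("whole-ring FSC(%.3f) resolution %.2f A",
                     config$fsc_threshold, res))
    list(full = full, resolution = res)
  })

  ## ---- layered-mask focusing ----
  focus <- stage("focus", {
    lspec <- layer_spec(config$layer$z_start, config$layer$z_end,
                        config$layer$transition_width)
    lmask <- make_layer_mask(n, px, lspec)
    masked <- apply_mask(ring_res$full, lmask)
    write_volume(masked, file.path(out_dir, "ring_recon_layer.mrc"))
    retained <- sum(masked$data) / sum(ring_res$full$data)
    log_line(state, "focus",
             sprintf("layer mask retains %.1f%% of reconstructed mass",
                     100 * retained))
    list(mass_retained = retained)
  })

  ## ---- subparticles: expand, recenter, extract ----
  frame <- subunit_frame(c(config$ring$ring_radius, 0, 0), nsym)
  box <- config$subparticle$box
  subp <- stage("subparticles", {
    ex <- symmetry_expand(observed, nsym)
    rc <- recenter_subparticles(ex, frame, n)
    extr <- extract_subparticles(sim$stack, rc, box)
    write_particle_table(extr$table,
                         file.path(out_dir, "subparticles.star"))
    write_stack(extr$stack, file.path(out_dir, "subparticles.mrc"))
    extr
  })

  ## ---- confined local refinement ----
  ## neighborhood reference: extracted windows see the adjacent subunits,
  ## so the consistent reference includes them
  subref <- make_toy_subunit_volume(sim$rspec, box, px, neighborhood = TRUE)
  refined <- stage("refine", {
    rf <- config$refine
    out <- local_refine(subp$stack, subref, subp$table,
                        rf$angular_range, rf$angular_step,
                        rf$shift_range, rf$shift_step, rounds = rf$rounds,
                        mask_radius = rf$mask_radius)
    write_particle_table(out, file.path(out_dir, "subparticles_refined.star"))
    out
  })

  ## ---- subparticle reconstructions and FSC before/after ----
  sub_fsc <- stage("fsc", {
    mask <- soft_sphere_mask(box, px, 0.42 * box * px, 4 * px)
    res_of <- function(tab) {
      halves <- reconstruct(subp$stack, tab, half_sets = TRUE)
      curve <- compute_fsc(halves[[1]], halves[[2]], mask)
      list(curve = curve,
           res = resolution_at(curve, config$fsc_threshold))
    }
    before <- res_of(subp$table)
    after <- res_of(refined)
    full_after <- reconstruct(subp$stack, refined)
    write_volume(full_after, file.path(out_dir, "subunit_recon.mrc"))
    write_fsc_tsv(after$curve, file.path(out_dir, "fsc_subunit.tsv"))
    log_line(state, "fsc",
             sprintf("subparticle FSC resolution %.2f A before, %.2f A after refinement",
                     before$res, after$res))
    list(before = before$res, after = after$res, volume = full_after)
  })

  ## ---- pose recovery vs ground truth ----
  recovery <- stage("recovery", {
    truth_sub <- recenter_subparticles(symmetry_expand(sim$truth, nsym),
                                       frame, n)
    ## excluded rows can differ between the truth and observed tables;
    ## compare on the common (particle, subunit) keys
    key <- function(t) paste(if (!is.null(t$source_image)) t$source_image
                             else t$image_index, t$subunit_index)
    common <- intersect(key(truth_sub), key(subp$table))
    it <- match(common, key(truth_sub))
    ang_err <- function(tab) {
      io <- match(common, key(tab))
      vapply(seq_along(common), function(j) {
        a <- io[j]; b <- it[j]
        Ra <- euler_to_matrix(tab$rot[a], tab$tilt[a], tab$psi[a])
        Rb <- euler_to_matrix(truth_sub$rot[b], truth_sub$tilt[b],
                              truth_sub$psi[b])
        tr <- sum(diag(t(Ra) %*% Rb))
        rad2deg(acos(pmin(1, pmax(-1, (tr - 1) / 2))))
      }, 0)
    }
    ## total in-plane shift error: fractional shifts are only comparable
    ## together with the integer window offsets
    shift_err <- function(tab) {
      io <- match(common, key(tab))
      tx <- truth_sub$shift_x[it] +
            (truth_sub$offset_x[it] - tab$offset_x[io]) * px
      ty <- truth_sub$shift_y[it] +
            (truth_sub$offset_y[it] - tab$offset_y[io]) * px
      pmax(abs(tab$shift_x[io] - tx), abs(tab$shift_y[io] - ty))
    }
    summ <- function(e) list(mean = mean(e), median = stats::median(e))
    list(angular_error_deg = list(before = summ(ang_err(subp$table)),
                                  after = summ(ang_err(refined))),
         shift_error_A = list(before = summ(shift_err(subp$table)),
                              after = summ(shift_err(refined))))
  })

  ## ---- composite assembly ----
  composite <- stage("assemble", {
    pl <- fit_subunit_positions(sub_fsc$volume, ring_res$full, nsym,
                                center = frame$center)
    sub_model <- {
      m <- sim$ring$model
      keep <- m$atoms$chain == "SUB0"
      atomic_model(transform_model(
        atomic_model(m$atoms[keep, ], m$chains[m$chains$chain == "SUB0", ]),
        transform_rt(diag(3), -frame$center))$atoms,
        m$chains[m$chains$chain == "SUB0", ])
    }
    comp <- assemble_ring(sub_model, pl)
    write_mmcif(comp, file.path(out_dir, "composite.cif"))
    diam <- ring_diameters(comp)
    angles <- vapply(pl$transforms, function(t)
      normalize_angle(rad2deg(atan2(t$rotation[2, 1], t$rotation[1, 1]))), 0)
    list(placement_angles = angles, scores = pl$scores, diameters = diam,
         model = comp)
  })

  ## ---- structural analyses on the composite ----
  analyses <- stage("analyze", {
    census <- model_census(composite$model)
    tm <- make_toy_models(seed = config$seed)
    sup <- superpose(tm$model_a, tm$model_b)
    list(census = census,
         toy_superposition = list(rmsd = sup$rmsd,
                                  n_aligned = sup$n_aligned))
  })

  report$resolutions <- list(whole_ring = ring_res$resolution,
                             subparticle_before = sub_fsc$before,
                             subparticle_after = sub_fsc$after)
  report$focus <- focus
  report$recovery <- recovery
  report$composite <- composite[c("placement_angles", "scores", "diameters")]
  report$analyses <- analyses
  arts <- list.files(out_dir, full.names = TRUE)
  arts <- arts[!grepl("report\\.json$|run\\.log$", arts)]
  report$manifest <- as.list(tools::md5sum(arts))
  names(report$manifest) <- basename(arts)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  log_line(state, "done", paste("report written to",
                                file.path(out_dir, "report.json")))
  invisible(report)
}
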