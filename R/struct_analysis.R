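## Structural measurements on (composite) atomic models: least-squares
## rigid superposition (Kabsch), interface contact cataloguing with SSE
## annotation, flexible-linker reachability, and model census.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation + translation that superposes the mobile
#' model (`model_a`) onto the reference (`model_b`) over matched CA pairs,
#' and reports the residual RMSD.
#'
#' @param model_a mobile [atomic_model()].
#' @param model_b reference [atomic_model()].
#' @param policy residue correspondence: "entity_copy_resno" matches by
#'   (entity, copy label, residue number), "chain_resno" by (chain id,
#'   residue number), "pairs" uses an explicit data.frame
#'   (chain_a, resno_a, chain_b, resno_b).
#' @param pairs pair list for policy "pairs".
#' @return object of class `superposition_result`: transform
#'   ([transform_rt()]), rmsd (Angstrom), n_aligned, per-residue deviations.
#' @export
superpose <- function(model_a, model_b,
                      policy = c("entity_copy_resno", "chain_resno", "pairs"),
                      pairs = NULL) {
  policy <- match.arg(policy)
  ca_a <- model_ca(model_a)
  ca_b <- model_ca(model_b)
  if (policy == "pairs") {
    if (is.null(pairs)) stop("policy 'pairs' requires a pair list")
    ia <- match(paste(pairs$chain_a, pairs$resno_a),
                paste(ca_a$chain, ca_a$resno))
    ib <- match(paste(pairs$chain_b, pairs$resno_b),
                paste(ca_b$chain, ca_b$resno))
    ok <- !is.na(ia) & !is.na(ib)
    ia <- ia[ok]; ib <- ib[ok]
  } else {
    key <- function(ca) {
      if (policy == "entity_copy_resno")
        paste(ca$entity, ca$copy_label, ca$resno, sep = "|")
      else paste(ca$chain, ca$resno, sep = "|")
    }
    ka <- key(ca_a); kb <- key(ca_b)
    common <- intersect(ka, kb)
    ia <- match(common, ka); ib <- match(common, kb)
  }
  if (length(ia) < 3)
    stop("need at least 3 matched CA pairs, got ", length(ia))
  X <- as.matrix(ca_a[ia, c("x", "y", "z")])
  Y <- as.matrix(ca_b[ib, c("x", "y", "z")])
  xc <- colMeans(X); yc <- colMeans(Y)
  H <- crossprod(sweep(X, 2, xc), sweep(Y, 2, yc))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  reflection <- d < 0
  tr <- as.numeric(yc - R %*% xc)
  fitted <- sweep(X %*% t(R), 2, tr, "+")
  dev <- sqrt(rowSums((fitted - Y)^2))
  res <- list(transform = transform_rt(R, tr),
              rmsd = sqrt(mean(dev^2)),
              n_aligned = length(ia),
              deviations = data.frame(chain = ca_a$chain[ia],
                                      resno = ca_a$resno[ia],
                                      deviation = dev),
              reflection_optimal = reflection)
  if (reflection)
    message("reflection would fit better; proper rotation enforced")
  class(res) <- "superposition_result"
  res
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition: RMSD %.3f A over %d aligned CA atoms\n",
              x$rmsd, x$n_aligned))
  invisible(x)
}

sse_label_for <- function(sse, chain, resno) {
  if (is.null(sse)) return(rep(NA_character_, length(resno)))
  out <- rep(NA_character_, length(resno))
  for (i in seq_len(nrow(sse))) {
    hit <- chain == sse$chain[i] & resno >= sse$start[i] & resno <= sse$end[i]
    out[hit] <- sse$label[i]
  }
  out
}

#' Find inter-chain residue contacts
#'
#' All residue pairs between two disjoint chain sets whose minimum
#' inter-atom distance is at or below the cutoff, found with a cell-list
#' search (expected O(n)).  Defaults: 4.5 A in all-atom mode, 8.0 A
#' between CA atoms in CA mode.  Residues are annotated with covering SSE
#' labels when the model carries annotations.
#'
#' @param model [atomic_model()].
#' @param chains_a,chains_b disjoint chain-id sets.
#' @param cutoff distance cutoff in Angstrom (mode-dependent default).
#' @param mode "all_atom" or "ca".
#' @return data.frame of class `contact_list`: chain_a, resno_a, sse_a,
#'   chain_b, resno_b, sse_b, distance, mode.
#' @export
find_contacts <- function(model, chains_a, chains_b, cutoff = NULL,
                          mode = c("all_atom", "ca")) {
  mode <- match.arg(mode)
  if (is.null(cutoff)) cutoff <- if (mode == "ca") 8.0 else 4.5
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (length(intersect(chains_a, chains_b)))
    stop("chain sets must be disjoint")
  known <- unique(model$atoms$chain)
  unknown <- setdiff(c(chains_a, chains_b), known)
  if (length(unknown))
    stop("unknown chain(s): ", paste(unknown, collapse = ", "))
  at <- model$atoms
  if (mode == "ca") at <- at[at$atom == "CA", ]
  A <- data.table::as.data.table(at[at$chain %in% chains_a,
                                    c("chain", "resno", "x", "y", "z")])
  B <- data.table::as.data.table(at[at$chain %in% chains_b,
                                    c("chain", "resno", "x", "y", "z")])
  if (!nrow(A) || !nrow(B)) return(empty_contacts(mode))
  cell <- function(v) as.integer(floor(v / cutoff))
  A[, `:=`(cx = cell(x), cy = cell(y), cz = cell(z),
           ia = .I)]
  B[, ib := .I]
  offs <- data.table::CJ(dx = -1:1, dy = -1:1, dz = -1:1)
  Bx <- B[rep(seq_len(nrow(B)), each = 27)]
  Bx[, `:=`(cx = cell(x) + rep(offs$dx, nrow(B)),
            cy = cell(y) + rep(offs$dy, nrow(B)),
            cz = cell(z) + rep(offs$dz, nrow(B)))]
  data.table::setkey(A, cx, cy, cz)
  cand <- A[Bx, on = c("cx", "cy", "cz"), nomatch = NULL,
            allow.cartesian = TRUE]
  if (!nrow(cand)) return(empty_contacts(mode))
  cand[, dist := sqrt((x - i.x)^2 + (y - i.y)^2 + (z - i.z)^2)]
  cand <- cand[dist <= cutoff]
  if (!nrow(cand)) return(empty_contacts(mode))
  res <- cand[, .(distance = min(dist)),
              by = .(chain_a = chain, resno_a = resno,
                     chain_b = i.chain, resno_b = i.resno)]
  res <- as.data.frame(res)
  res$sse_a <- sse_label_for(model$sse, res$chain_a, res$resno_a)
  res$sse_b <- sse_label_for(model$sse, res$chain_b, res$resno_b)
  res$mode <- mode
  res <- res[order(res$chain_a, res$resno_a, res$chain_b, res$resno_b),
             c("chain_a", "resno_a", "sse_a", "chain_b", "resno_b", "sse_b",
               "distance", "mode")]
  rownames(res) <- NULL
  class(res) <- c("contact_list", "data.frame")
  res
}

empty_contacts <- function(mode) {
  res <- data.frame(chain_a = character(), resno_a = integer(),
                    sse_a = character(), chain_b = character(),
                    resno_b = integer(), sse_b = character(),
                    distance = numeric(), mode = character())
  class(res) <- c("contact_list", "data.frame")
  res
}

#' Flexible-linker reachability
#'
#' Geometric feasibility of an n-residue disordered linker bridging two
#' anchor residues: the linker spans at most n_steps x per-residue span
#' (3.8 A trans CA-CA), so the bridge is feasible iff the Euclidean anchor
#' distance does not exceed that bound.  Distances are measured in the
#' supplied (possibly composite) coordinate frame, so the same anchors can
#' be tested within one subunit and across assembled neighbors.
#'
#' @param model [atomic_model()].
#' @param anchor_a,anchor_b lists (chain, resno).
#' @param per_step_span maximal CA-CA span per residue step, Angstrom.
#' @param allow_cross_entity permit anchors on different entities.
#' @return object of class `reachability_report`: distance, n_steps,
#'   per_step_span, max_span, feasible.
#' @export
linker_reachability <- function(model, anchor_a, anchor_b,
                                per_step_span = 3.8,
                                allow_cross_entity = FALSE) {
  ca <- model_ca(model)
  pick <- function(an) {
    i <- which(ca$chain == an[[1]] & ca$resno == an[[2]])
    if (!length(i))
      stop("anchor ", an[[1]], ":", an[[2]], " not found")
    ca[i[1], ]
  }
  a <- pick(anchor_a); b <- pick(anchor_b)
  if (!allow_cross_entity && !identical(a$entity, b$entity))
    stop("anchors lie on different entities (", a$entity, " vs ", b$entity,
         "); pass allow_cross_entity = TRUE to override")
  d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  n_steps <- abs(b$resno - a$resno)
  max_span <- n_steps * per_step_span
  structure(list(anchor_a = anchor_a, anchor_b = anchor_b,
                 distance = d, n_steps = n_steps,
                 per_step_span = per_step_span, max_span = max_span,
                 feasible = d <= max_span),
            class = "reachability_report")
}

#' @export
print.reachability_report <- function(x, ...) {
  cat(sprintf(
    "linker reachability: %.1f A over %d residues (max span %.1f A) -> %s\n",
    x$distance, x$n_steps, x$max_span,
    if (x$feasible) "feasible" else "infeasible"))
  invisible(x)
}

#' Model census
#'
#' Chain, entity and residue counts plus an approximate molecular mass
#' (residues x mean residue mass, 110 Da default).
#'
#' @param model [atomic_model()].
#' @param exclude_entities entity names to leave out (e.g. a neighboring
#'   ring's fragment included in a deposition).
#' @param residue_mass mean residue mass in Da.
#' @return list(n_chains, n_entities, n_residues, mass_da).
#' @export
model_census <- function(model, exclude_entities = NULL, residue_mass = 110) {
  ca <- model_ca(model)
  if (!is.null(exclude_entities))
    ca <- ca[!(ca$entity %in% exclude_entities), ]
  list(n_chains = length(unique(ca$chain)),
       n_entities = length(unique(ca$entity)),
       n_residues = nrow(ca),
       mass_da = nrow(ca) * residue_mass)
}
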