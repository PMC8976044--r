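## Atomic models: chains -> residues -> atoms, with entity names, copy
## labels and optional secondary-structure (SSE) annotations.
##
## Internally an atomic_model is a list of plain data.frames:
##   atoms:  chain, resno, resname, atom, element, x, y, z   (Angstrom)
##   chains: chain, entity, copy_label
##   sse:    label, chain, start, end
## Readers exist for PDB and mmCIF; mmCIF is preferred for large models
## (> 62 chains or > 99,999 atoms exceed the PDB fixed columns).

#' Construct an atomic model
#'
#' @param atoms data.frame with columns chain, resno, resname, atom, x, y, z
#'   (element optional).
#' @param chains data.frame with columns chain, entity, copy_label; defaults
#'   to one entity per chain id.
#' @param sse optional data.frame with columns label, chain, start, end.
#' @return object of class `atomic_model`.
#' @export
atomic_model <- function(atoms, chains = NULL, sse = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms lack column(s): ", paste(miss, collapse = ", "))
  if (is.null(atoms$element))
    atoms$element <- substring(trimws(atoms$atom), 1, 1)
  atoms$resno <- as.integer(atoms$resno)
  if (is.null(chains)) {
    chains <- data.frame(chain = unique(atoms$chain),
                         entity = unique(atoms$chain),
                         copy_label = NA_character_,
                         stringsAsFactors = FALSE)
  }
  chains <- as.data.frame(chains, stringsAsFactors = FALSE)
  if (is.null(chains$copy_label)) chains$copy_label <- NA_character_
  ## residue numbers strictly increasing within each chain (on CA records)
  ca <- atoms[atoms$atom == "CA", ]
  for (ch in unique(ca$chain)) {
    r <- ca$resno[ca$chain == ch]
    if (any(diff(r) <= 0))
      stop("residue numbers are not strictly increasing in chain ", ch)
  }
  if (!is.null(sse)) {
    sse <- as.data.frame(sse, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(sse))) {
      rr <- ca$resno[ca$chain == sse$chain[i]]
      if (!length(rr) || sse$start[i] < min(rr) || sse$end[i] > max(rr))
        stop("SSE range ", sse$label[i], " lies outside chain ", sse$chain[i])
    }
  }
  structure(list(atoms = atoms, chains = chains, sse = sse),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  ca <- model_ca(x)
  cat(sprintf("atomic_model: %d chains, %d entities, %d residues (CA), %d atoms\n",
              nrow(x$chains), length(unique(x$chains$entity)),
              nrow(ca), nrow(x$atoms)))
  invisible(x)
}

#' Extract the C-alpha trace of a model
#'
#' @param model [atomic_model()].
#' @return data.frame chain, resno, resname, x, y, z (one row per residue
#'   with a CA atom), joined with entity and copy_label.
#' @export
model_ca <- function(model) {
  ca <- model$atoms[model$atoms$atom == "CA",
                    c("chain", "resno", "resname", "x", "y", "z")]
  idx <- match(ca$chain, model$chains$chain)
  ca$entity <- model$chains$entity[idx]
  ca$copy_label <- model$chains$copy_label[idx]
  rownames(ca) <- NULL
  ca
}

#' Apply a rigid transform to a model
#' @param model [atomic_model()].
#' @param rt [transform_rt()].
#' @return transformed [atomic_model()].
#' @export
transform_model <- function(model, rt) {
  xyz <- apply_rt(rt, as.matrix(model$atoms[, c("x", "y", "z")]))
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

## ---- PDB ----

#' Read a PDB file
#'
#' ATOM/HETATM records only; chains with no CA atom are dropped with a
#' warning. Entity names default to chain ids unless `entity_map`
#' (named character vector, chain -> entity) is supplied.
#'
#' @param path PDB file.
#' @param entity_map optional named character vector chain id -> entity name.
#' @param copy_map optional named character vector chain id -> copy label.
#' @return [atomic_model()].
#' @export
read_pdb <- function(path, entity_map = NULL, copy_map = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(lines)) stop("no ATOM records in ", path)
  atoms <- data.frame(
    chain = trimws(substring(lines, 22, 22)),
    resno = as.integer(substring(lines, 23, 26)),
    resname = trimws(substring(lines, 18, 20)),
    atom = trimws(substring(lines, 13, 16)),
    element = trimws(substring(lines, 77, 78)),
    x = as.numeric(substring(lines, 31, 38)),
    y = as.numeric(substring(lines, 39, 46)),
    z = as.numeric(substring(lines, 47, 54)),
    stringsAsFactors = FALSE)
  finish_model(atoms, entity_map, copy_map)
}

finish_model <- function(atoms, entity_map, copy_map, entity_by_chain = NULL) {
  has_ca <- unique(atoms$chain[atoms$atom == "CA"])
  dropped <- setdiff(unique(atoms$chain), has_ca)
  if (length(dropped)) {
    warning("dropping chain(s) with no CA atoms: ",
            paste(dropped, collapse = ", "))
    atoms <- atoms[atoms$chain %in% has_ca, ]
  }
  chs <- unique(atoms$chain)
  ent <- if (!is.null(entity_map)) unname(entity_map[chs])
         else if (!is.null(entity_by_chain)) unname(entity_by_chain[chs])
         else chs
  ent[is.na(ent)] <- chs[is.na(ent)]
  cp <- if (!is.null(copy_map)) unname(copy_map[chs]) else NA_character_
  atomic_model(atoms, data.frame(chain = chs, entity = ent, copy_label = cp,
                                 stringsAsFactors = FALSE))
}

#' Write a PDB file
#' @param model [atomic_model()].
#' @param path output file.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  if (length(unique(a$chain)) > 62 || nrow(a) > 99999)
    stop("model too large for PDB fixed columns; use write_mmcif()")
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(a)),
    ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom),
    a$resname, a$chain, a$resno, a$x, a$y, a$z, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

## ---- mmCIF ----

cif_tokenize <- function(text) {
  ## tokenizer for the subset of CIF syntax found in coordinate files:
  ## whitespace-separated values, '...'/"..." quoting, # comments,
  ## semicolon text fields at line starts.
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  toks <- character(0); buf <- list(); k <- 0
  i <- 1
  while (i <= length(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ";")) {            # multi-line text field
      val <- substring(ln, 2)
      i <- i + 1
      while (i <= length(lines) && !startsWith(lines[i], ";")) {
        val <- paste(val, lines[i]); i <- i + 1
      }
      k <- k + 1; buf[[k]] <- val
      i <- i + 1
      next
    }
    m <- gregexpr("'[^']*'|\"[^\"]*\"|#.*$|[^[:space:]]+", ln)[[1]]
    if (m[1] != -1) {
      parts <- regmatches(ln, list(m))[[1]]
      parts <- parts[!startsWith(parts, "#")]
      if (length(parts)) { k <- k + 1; buf[[k]] <- parts }
    }
    i <- i + 1
  }
  toks <- unlist(buf, use.names = FALSE)
  if (is.null(toks)) character(0) else toks
}

cif_unquote <- function(x) {
  q <- (startsWith(x, "'") & endsWith(x, "'")) |
       (startsWith(x, "\"") & endsWith(x, "\""))
  x[q] <- substring(x[q], 2, nchar(x[q]) - 1)
  x
}

cif_parse <- function(path) {
  toks <- cif_tokenize(paste(readLines(path, warn = FALSE), collapse = "\n"))
  items <- list(); loops <- list()
  i <- 1; n <- length(toks)
  while (i <= n) {
    t <- toks[i]
    if (startsWith(t, "data_")) { i <- i + 1; next }
    if (t == "loop_") {
      tags <- character(0); i <- i + 1
      while (i <= n && startsWith(toks[i], "_")) { tags <- c(tags, toks[i]); i <- i + 1 }
      vals <- character(0); j <- i
      while (j <= n && !startsWith(toks[j], "_") && toks[j] != "loop_" &&
             !startsWith(toks[j], "data_")) j <- j + 1
      vals <- toks[i:(j - 1)]
      i <- j
      nr <- length(vals) %/% length(tags)
      m <- matrix(cif_unquote(vals[seq_len(nr * length(tags))]),
                  ncol = length(tags), byrow = TRUE)
      df <- as.data.frame(m, stringsAsFactors = FALSE)
      names(df) <- tags
      loops[[length(loops) + 1]] <- df
    } else if (startsWith(t, "_")) {
      items[[t]] <- cif_unquote(toks[i + 1])
      i <- i + 2
    } else i <- i + 1
  }
  list(items = items, loops = loops)
}

cif_find_loop <- function(parsed, prefix) {
  for (df in parsed$loops)
    if (any(startsWith(names(df), prefix))) return(df)
  NULL
}

#' Read an mmCIF coordinate file
#'
#' Parses `_atom_site` (coordinates, auth chain/residue ids) and, when
#' present, `_entity.pdbx_description` for entity names. Deposited files may
#' not record inner/outer copy distinctions; supply `copy_map` to annotate.
#'
#' @param path mmCIF file.
#' @param entity_map optional chain id -> entity name override.
#' @param copy_map optional chain id -> copy label map.
#' @return [atomic_model()].
#' @export
read_mmcif <- function(path, entity_map = NULL, copy_map = NULL) {
  p <- cif_parse(path)
  as_ <- cif_find_loop(p, "_atom_site.")
  if (is.null(as_)) stop("no _atom_site loop in ", path)
  g <- function(tag, alt = NULL) {
    v <- as_[[paste0("_atom_site.", tag)]]
    if (is.null(v) && !is.null(alt)) v <- as_[[paste0("_atom_site.", alt)]]
    v
  }
  chain <- g("auth_asym_id", "label_asym_id")
  resno <- g("auth_seq_id", "label_seq_id")
  atoms <- data.frame(
    chain = chain,
    resno = suppressWarnings(as.integer(resno)),
    resname = g("label_comp_id", "auth_comp_id"),
    atom = g("label_atom_id", "auth_atom_id"),
    element = g("type_symbol") %||% "",
    x = as.numeric(g("Cartn_x")), y = as.numeric(g("Cartn_y")),
    z = as.numeric(g("Cartn_z")),
    entity_id = g("label_entity_id") %||% NA_character_,
    stringsAsFactors = FALSE)
  grp <- g("group_PDB")
  if (!is.null(grp)) atoms <- atoms[grp == "ATOM", ]
  atoms <- atoms[!is.na(atoms$resno), ]
  if (!nrow(atoms)) stop("no polymer ATOM records in ", path)
  ent_by_chain <- NULL
  ent <- cif_find_loop(p, "_entity.")
  eid <- if (!is.null(ent)) ent[["_entity.id"]] else p$items[["_entity.id"]]
  edesc <- if (!is.null(ent)) ent[["_entity.pdbx_description"]]
           else p$items[["_entity.pdbx_description"]]
  if (!is.null(eid) && !is.null(edesc) && !all(is.na(atoms$entity_id))) {
    desc <- stats::setNames(trimws(edesc), eid)
    ec <- tapply(atoms$entity_id, atoms$chain, function(v) v[1])
    ent_by_chain <- stats::setNames(unname(desc[ec]), names(ec))
  }
  atoms$entity_id <- NULL
  finish_model(atoms, entity_map, copy_map, ent_by_chain)
}

#' Write an mmCIF coordinate file
#'
#' Emits `_entity` descriptions and an `_atom_site` loop sufficient to round
#' trip through [read_mmcif()].
#'
#' @param model [atomic_model()].
#' @param path output file.
#' @export
write_mmcif <- function(model, path) {
  a <- model$atoms
  ents <- unique(model$chains$entity)
  eid <- match(model$chains$entity, ents)
  chain_eid <- stats::setNames(eid, model$chains$chain)
  con <- c("data_ringblock_model", "#", "loop_",
           "_entity.id", "_entity.pdbx_description",
           sprintf("%d '%s'", seq_along(ents), ents),
           "#", "loop_",
           "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.type_symbol", "_atom_site.label_atom_id",
           "_atom_site.label_comp_id", "_atom_site.label_asym_id",
           "_atom_site.label_entity_id", "_atom_site.auth_asym_id",
           "_atom_site.auth_seq_id",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           sprintf("ATOM %d %s %s %s %s %d %s %d %.3f %.3f %.3f",
                   seq_len(nrow(a)), a$element, a$atom, a$resname, a$chain,
                   chain_eid[a$chain], a$chain, a$resno, a$x, a$y, a$z),
           "#")
  writeLines(con, path)
  invisible(path)
}

#' Read an atomic model (PDB or mmCIF by extension)
#' @param path file ending in .pdb, .ent, .cif or .mmcif.
#' @param ... passed to [read_pdb()] / [read_mmcif()].
#' @return [atomic_model()].
#' @export
read_model <- function(path, ...) {
  if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) read_mmcif(path, ...)
  else read_pdb(path, ...)
}

#' Write an atomic model (PDB or mmCIF by extension)
#' @param model [atomic_model()].
#' @param path file ending in .pdb or .cif/.mmcif.
#' @export
write_model <- function(model, path) {
  if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
    write_mmcif(model, path)
  else write_pdb(model, path)
}
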