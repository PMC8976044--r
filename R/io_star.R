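## Particle metadata tables and their STAR-dialect serialization.
##
## A particle table is a data.frame (class "particle_table") with one row per
## particle and the canonical columns below; anything else round-trips as an
## opaque extra column.  On disk the table is a single loop_ block with
## RELION-style tags so real-world tables can be ingested.
##
## Shift convention: shift_x/shift_y are the translation (in Angstrom) that
## re-centers the observed particle, i.e. the projected reference appears in
## the image displaced by (-shift_x, -shift_y).  This matches the dominant
## particle-metadata dialect and makes subparticle re-centering arithmetic
## (new shift = old shift - projected subunit offset) exact.

PT_COLUMNS <- c("image_name", "image_index", "rot", "tilt", "psi",
                "shift_x", "shift_y", "defocus_u", "defocus_v",
                "astig_angle", "pixel_size", "group_id", "subunit_index")

STAR_TAGS <- c(rot = "_rlnAngleRot", tilt = "_rlnAngleTilt",
               psi = "_rlnAnglePsi",
               shift_x = "_rlnOriginXAngst", shift_y = "_rlnOriginYAngst",
               defocus_u = "_rlnDefocusU", defocus_v = "_rlnDefocusV",
               astig_angle = "_rlnDefocusAngle",
               pixel_size = "_rlnImagePixelSize",
               group_id = "_rlnGroupNumber",
               subunit_index = "_rbSubunitIndex")

#' Construct a particle table
#'
#' @param df data.frame carrying at least the pose (rot, tilt, psi), shifts
#'   (shift_x, shift_y, Angstrom), CTF (defocus_u, defocus_v, astig_angle)
#'   and pixel_size columns. Missing bookkeeping columns (image_name,
#'   image_index, group_id) are filled with defaults; subunit_index may be
#'   absent (NA).
#' @param bin_level provenance note (binning level of the source images).
#' @return data.frame of class `particle_table`; rot/psi normalized to
#'   (-180, 180].
#' @export
particle_table <- function(df, bin_level = 1L) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("rot", "tilt", "psi", "shift_x", "shift_y",
            "defocus_u", "defocus_v", "pixel_size")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("particle table is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(df$astig_angle)) df$astig_angle <- 0
  if (is.null(df$image_name)) df$image_name <- "stack.mrcs"
  if (is.null(df$image_index)) df$image_index <- seq_len(nrow(df))
  if (is.null(df$group_id)) df$group_id <- 1L
  if (is.null(df$subunit_index)) df$subunit_index <- NA_integer_
  df$rot <- normalize_angle(df$rot)
  df$psi <- normalize_angle(df$psi)
  df$astig_angle <- normalize_angle(df$astig_angle)
  if (any(df$tilt < 0 | df$tilt > 180))
    stop("tilt angles must lie in [0, 180]")
  if (any(df$defocus_u <= 0 | df$defocus_v <= 0))
    stop("defocus values must be positive")
  if (any(df$pixel_size <= 0)) stop("pixel_size must be positive")
  if (length(unique(df$pixel_size)) != 1)
    stop("all records in a particle table must share one pixel_size")
  extra <- setdiff(names(df), PT_COLUMNS)
  df <- df[, c(PT_COLUMNS, extra), drop = FALSE]
  attr(df, "bin_level") <- bin_level
  class(df) <- c("particle_table", "data.frame")
  df
}

star_quote <- function(x) {
  x <- as.character(x)
  bad <- grepl("[[:space:]]", x) | x == ""
  x[bad] <- paste0("\"", x[bad], "\"")
  x
}

star_fmt_col <- function(x) {
  if (is.numeric(x) && !is.integer(x)) sprintf("%.6f", x)
  else star_quote(x)
}

#' Write a particle table as a STAR-dialect file
#'
#' Single `data_particles` block with one `loop_`. Numeric fields are
#' written with 6 decimals (defocus round-trips to well under 1e-3 A);
#' extra columns are written verbatim after the canonical tags.
#'
#' @param table [particle_table()].
#' @param path output file.
#' @export
write_particle_table <- function(table, path) {
  if (nrow(table) == 0) stop("refusing to write an empty particle table")
  tab <- as.data.frame(table)
  ## absent subunit assignment is represented by dropping the tag
  all_na <- vapply(tab, function(v) all(is.na(v)), TRUE)
  tab <- tab[!all_na]
  if (anyNA(tab)) stop("particle table contains partial NA columns")
  tab$image_ref <- sprintf("%06d@%s", tab$image_index, tab$image_name)
  canon <- intersect(names(STAR_TAGS), names(tab))
  extra <- setdiff(names(tab), c(PT_COLUMNS, "image_ref"))
  cols <- c("image_ref", canon, extra)
  tags <- c("_rlnImageName", unname(STAR_TAGS[canon]),
            paste0("_rb_", extra))
  out <- c("", "data_particles", "", "loop_",
           sprintf("%s #%d", tags, seq_along(tags)))
  body <- do.call(paste, c(lapply(tab[cols], star_fmt_col), sep = " "))
  writeLines(c(out, body, ""), path)
  invisible(path)
}

star_tokenize <- function(line) {
  scan(text = line, what = "character", quiet = TRUE)
}

#' Read a STAR-dialect particle table
#'
#' Accepts a loop-structured block with RELION-style tags. Unknown tags are
#' preserved as opaque extra columns; rot/psi are normalized to (-180, 180].
#'
#' @param path STAR file.
#' @return [particle_table()].
#' @export
read_particle_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  li <- which(lines == "loop_")
  if (!length(li)) stop("no loop_ block found in ", path)
  i <- li[1] + 1
  tags <- character()
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    tags <- c(tags, sub("[[:space:]]*#.*$", "", lines[i]))
    i <- i + 1
  }
  rows <- lines[i:length(lines)]
  rows <- rows[!startsWith(rows, "data_")]
  cells <- lapply(rows, star_tokenize)
  bad <- which(lengths(cells) != length(tags))
  if (length(bad))
    stop("row ", bad[1], " has ", lengths(cells)[bad[1]],
         " fields, expected ", length(tags))
  m <- as.data.frame(do.call(rbind, cells), stringsAsFactors = FALSE)
  names(m) <- tags
  tag2col <- c(stats::setNames(names(STAR_TAGS), STAR_TAGS))
  df <- list()
  for (tg in tags) {
    col <- if (tg %in% names(tag2col)) tag2col[[tg]]
           else if (tg == "_rlnImageName") "image_ref"
           else sub("^_rb_", "", tg)
    v <- m[[tg]]
    num <- suppressWarnings(as.numeric(v))
    df[[col]] <- if (!anyNA(num)) num else v
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!is.null(df$image_ref)) {
    parts <- regmatches(df$image_ref, regexpr("@", df$image_ref),
                        invert = TRUE)
    df$image_index <- as.integer(vapply(parts, `[`, "", 1))
    df$image_name <- vapply(parts, `[`, "", 2)
    df$image_ref <- NULL
  }
  need <- c("rot", "tilt", "psi", "shift_x", "shift_y",
            "defocus_u", "defocus_v")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("STAR table lacks mandatory column(s): ",
         paste(STAR_TAGS[miss], collapse = ", "))
  if (is.null(df$pixel_size))
    stop("STAR table lacks mandatory column: ", STAR_TAGS[["pixel_size"]])
  if (!is.null(df$group_id)) df$group_id <- as.integer(df$group_id)
  if (!is.null(df$subunit_index) && is.numeric(df$subunit_index))
    df$subunit_index <- as.integer(df$subunit_index)
  particle_table(df)
}

#' @export
print.particle_table <- function(x, ...) {
  cat(sprintf("particle_table: %d records @ %.4f A/pixel (bin %s)\n",
              nrow(x), x$pixel_size[1],
              as.character(attr(x, "bin_level") %||% 1)))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Binned pixel size bookkeeping
#'
#' The arithmetic behind multi-level binned processing: a detector pixel of
#' `unbinned` Angstrom binned by integer factor `bin` images at
#' `unbinned * bin` Angstrom per pixel (e.g. 0.6935 A super-resolution
#' pixels give 1.387 A at bin 2 and 2.774 A at bin 4).
#'
#' @param unbinned unbinned pixel size in Angstrom.
#' @param bin integer binning factor >= 1.
#' @return binned pixel size in Angstrom.
#' @export
bin_pixel_size <- function(unbinned, bin) {
  stopifnot(unbinned > 0, bin >= 1, bin == round(bin))
  unbinned * bin
}
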