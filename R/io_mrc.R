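## MRC2014 volume / stack input and output (mode 2, 32-bit float only).
## Header layout follows the MRC2014 standard: 1024-byte header, little
## endian, column-major data with x fastest.  Only the fields the pipeline
## needs are interpreted (dimensions, mode, cell size for the pixel size,
## axis order 1/2/3, ispg, machine stamp).

#' Density volume on a cubic voxel grid
#'
#' Wraps an N x N x N numeric array with a physical pixel size. The physical
#' origin sits at voxel index (N/2, N/2, N/2) (0-based), matching the
#' centered-FFT convention used throughout.
#'
#' @param data cubic numeric array.
#' @param pixel_size voxel edge in Angstrom.
#' @return object of class `volume_grid`.
#' @export
volume_grid <- function(data, pixel_size) {
  d <- dim(data)
  if (length(d) != 3 || length(unique(d)) != 1)
    stop("volume must be a cubic N x N x N array")
  if (d[1] %% 2 != 0) stop("grid size N must be even")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  structure(list(data = data, pixel_size = as.numeric(pixel_size)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  n <- dim(x$data)[1]
  cat(sprintf("volume_grid: %d^3 voxels @ %.4f A/voxel (box %.1f A)\n",
              n, x$pixel_size, n * x$pixel_size))
  invisible(x)
}

#' Stack of square particle images
#'
#' @param data N x N x P numeric array (P images).
#' @param pixel_size pixel edge in Angstrom.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size) {
  d <- dim(data)
  if (length(d) == 2) { dim(data) <- c(d, 1L); d <- dim(data) }
  if (length(d) != 3 || d[1] != d[2]) stop("stack must be N x N x P")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  structure(list(data = data, pixel_size = as.numeric(pixel_size)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d images of %d x %d @ %.4f A/pixel\n",
              d[3], d[1], d[2], x$pixel_size))
  invisible(x)
}

mrc_write_raw <- function(data, pixel_size, path, is_stack) {
  d <- dim(data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                                  # nx ny nz
  wi(2)                                  # mode 2: float32
  wi(c(0, 0, 0))                         # nxstart
  wi(d)                                  # mx my mz
  wf(d * pixel_size)                     # cella
  wf(c(90, 90, 90))                      # cellb
  wi(c(1, 2, 3))                         # mapc mapr maps
  wf(c(min(data), max(data), mean(data)))
  wi(if (is_stack) 0 else 1)             # ispg
  wi(0)                                  # nsymbt
  writeBin(raw(100), con)                # extra (incl. exttyp/nversion zeroed)
  wf(c(0, 0, 0))                         # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little endian
  wf(stats::sd(as.numeric(data)))        # rms
  wi(0)                                  # nlabl
  writeBin(raw(800), con)                # labels
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

mrc_read_raw <- function(path, pixel_size_override = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 1024)
  ri <- function(off, n = 1) readBin(hdr[(off + 1):(off + 4 * n)], "integer",
                                     n, size = 4, endian = "little")
  rf <- function(off, n = 1) readBin(hdr[(off + 1):(off + 4 * n)], "numeric",
                                     n, size = 4, endian = "little")
  d <- ri(0, 3)
  mode <- ri(12)
  if (mode != 2) stop("only MRC mode 2 (32-bit float) is supported, got mode ", mode)
  m <- ri(28, 3)
  cella <- rf(40, 3)
  nsymbt <- ri(92)
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  px <- if (m[1] > 0 && cella[1] > 0) cella[1] / m[1] else NA_real_
  if (!is.finite(px) || px <= 0) {
    if (is.null(pixel_size_override))
      stop("MRC header carries no pixel size; supply pixel_size_override")
    px <- pixel_size_override
  }
  vals <- readBin(con, "numeric", prod(d), size = 4, endian = "little")
  list(data = array(vals, dim = d), pixel_size = px, ispg = ri(88))
}

#' Read an MRC density volume
#'
#' @param path MRC file (mode 2, cubic).
#' @param pixel_size_override used when the header carries no pixel size.
#' @return [volume_grid()].
#' @export
read_volume <- function(path, pixel_size_override = NULL) {
  r <- mrc_read_raw(path, pixel_size_override)
  d <- dim(r$data)
  if (length(unique(d)) != 1)
    stop("MRC file is not cubic (", paste(d, collapse = "x"),
         "); read_stack() reads image stacks")
  volume_grid(r$data, r$pixel_size)
}

#' Write an MRC density volume
#'
#' Round trips with [read_volume()]: voxel values at float32 precision,
#' pixel size to <= 1e-6 relative.
#'
#' @param volume [volume_grid()].
#' @param path output file.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_grid"))
  mrc_write_raw(volume$data, volume$pixel_size, path, is_stack = FALSE)
}

#' Read an MRC image stack
#' @param path MRC stack file.
#' @param pixel_size_override used when the header carries no pixel size.
#' @return [image_stack()].
#' @export
read_stack <- function(path, pixel_size_override = NULL) {
  r <- mrc_read_raw(path, pixel_size_override)
  image_stack(r$data, r$pixel_size)
}

#' Write an MRC image stack
#' @param stack [image_stack()].
#' @param path output file.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  mrc_write_raw(stack$data, stack$pixel_size, path, is_stack = TRUE)
}
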