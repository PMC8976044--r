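## Layered z-masks with raised-cosine transitions and soft spherical masks.
## A layer is a physical z-interval of the reference frame (the ring /
## symmetry axis is z); each boundary carries a cosine ramp of width w
## centered on the boundary, so contiguous layers sharing a boundary are
## exactly complementary and sum to one.

#' Layer specification
#'
#' @param z_start,z_end physical z-interval in Angstrom (z = 0 at the grid
#'   center).
#' @param transition_width ramp width w in Angstrom; the ramp spans
#'   \[b - w/2, b + w/2\] around each boundary b.
#' @return object of class `layer_spec`.
#' @export
layer_spec <- function(z_start, z_end, transition_width = 0) {
  if (!(z_start < z_end)) stop("z_start must be < z_end")
  if (transition_width < 0) stop("transition_width must be >= 0")
  if (transition_width > (z_end - z_start))
    stop("transition_width cannot exceed the layer thickness")
  structure(list(z_start = z_start, z_end = z_end,
                 transition_width = transition_width),
            class = "layer_spec")
}

## raised-cosine step: 0 below b - w/2, 1 above b + w/2, 0.5 at b
rc_step <- function(z, b, w) {
  if (w == 0) return(as.numeric(z > b))
  up <- sin(pi * (z - (b - w / 2)) / (2 * w))^2
  ifelse(z <= b - w / 2, 0, ifelse(z >= b + w / 2, 1, up))
}

#' Build a layered z-mask
#'
#' Values are 1 strictly inside the layer, 0 outside, with raised-cosine
#' ramps across both boundaries (0.5 exactly at each boundary); constant in
#' x and y.  Contiguous layers sharing boundaries and w form a partition of
#' unity.
#'
#' @param grid_n grid size (even).
#' @param pixel_size Angstrom per voxel.
#' @param layer [layer_spec()].
#' @return [volume_grid()] with values in \[0, 1\].
#' @export
make_layer_mask <- function(grid_n, pixel_size, layer) {
  z <- (seq_len(grid_n) - 1 - grid_n %/% 2) * pixel_size
  w <- layer$transition_width
  lo <- layer$z_start - w / 2
  hi <- layer$z_end + w / 2
  if (max(z) < lo || min(z) > hi)
    stop("layer [", layer$z_start, ", ", layer$z_end,
         "] A does not intersect the grid (z range ",
         round(min(z), 1), " to ", round(max(z), 1), " A)")
  prof <- if (w == 0) as.numeric(z > layer$z_start & z < layer$z_end)
          else rc_step(z, layer$z_start, w) * (1 - rc_step(z, layer$z_end, w))
  volume_grid(array(rep(prof, each = grid_n * grid_n),
                    c(grid_n, grid_n, grid_n)),
              pixel_size)
}

#' Apply a mask to a volume
#'
#' @param volume,mask [volume_grid()] on the same grid.
#' @return voxelwise product as a [volume_grid()].
#' @export
apply_mask <- function(volume, mask) {
  if (!all(dim(volume$data) == dim(mask$data)))
    stop("volume and mask have different grid sizes")
  volume_grid(volume$data * mask$data, volume$pixel_size)
}

#' Soft spherical mask
#'
#' 1 inside radius - w/2, 0 outside radius + w/2, radial raised-cosine ramp
#' in between (0.5 exactly at `radius`).
#'
#' @param grid_n grid size (even).
#' @param pixel_size Angstrom per voxel.
#' @param radius sphere radius in Angstrom.
#' @param transition_width ramp width in Angstrom.
#' @param center sphere center in Angstrom (grid-center origin).
#' @return [volume_grid()] with values in \[0, 1\].
#' @export
soft_sphere_mask <- function(grid_n, pixel_size, radius,
                             transition_width = 0, center = c(0, 0, 0)) {
  ax <- (seq_len(grid_n) - 1 - grid_n %/% 2) * pixel_size
  dx2 <- (ax - center[1])^2
  dy2 <- (ax - center[2])^2
  dz2 <- (ax - center[3])^2
  r <- sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
  volume_grid(1 - rc_step(r, radius, transition_width), pixel_size)
}

## soft circular disc for in-plane SNR definitions
soft_disc_mask <- function(n, radius_px, width_px = 5) {
  ax <- seq_len(n) - 1 - n %/% 2
  r <- sqrt(outer(ax^2, ax^2, `+`))
  1 - rc_step(r, radius_px, width_px)
}
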