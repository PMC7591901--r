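#' Voxel grid specification
#'
#' Geometry of the 3D image a structure becomes: cubic tiles of
#' `cube_size` voxels per edge, `voxel_size` angstroms per voxel, tiled
#' across large proteins with `stride` voxels of overlap step, and a
#' Gaussian atomic density truncated at `r_cutoff` angstroms. The channel
#' scheme fixes the number of image channels.
#'
#' @param cube_size Voxels per tile edge (default 64). Must be divisible
#'   by the detector's output resolution of 8 cells per axis.
#' @param voxel_size Angstroms per voxel per axis (default 1.0).
#' @param stride Tiling stride in voxels (default 48).
#' @param r_cutoff Density cutoff in angstroms (default 4.0).
#' @param channel_scheme Channel scheme name (see [get_channel_scheme()]).
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(cube_size = 64L, voxel_size = 1.0, stride = 48L,
                      r_cutoff = 4.0, channel_scheme = "default") {
  cube_size <- as.integer(cube_size)
  stride <- as.integer(stride)
  if (cube_size %% 8L != 0L) rlang::abort("cube_size must be divisible by 8")
  if (stride > cube_size) rlang::abort("stride must be <= cube_size")
  if (r_cutoff <= 0) rlang::abort("r_cutoff must be positive")
  if (voxel_size <= 0) rlang::abort("voxel_size must be positive")
  structure(
    list(cube_size = cube_size, voxel_size = voxel_size, stride = stride,
         r_cutoff = r_cutoff, channel_scheme = channel_scheme,
         n_channels = channel_scheme_size(channel_scheme)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d^3 voxels of %.2f A, stride %d, r_cutoff %.1f A, %d channels (%s)\n",
    x$cube_size, x$voxel_size, x$stride, x$r_cutoff, x$n_channels,
    x$channel_scheme))
  invisible(x)
}

#' Truncated Gaussian atomic density
#'
#' The density an atom contributes at distance `r`:
#' `exp(-r^2 / 2)` for `r <= r_cutoff` and exactly 0 beyond the cutoff
#' (atoms exactly at the cutoff contribute).
#'
#' @param r Distance(s) in angstroms; must be non-negative.
#' @param r_cutoff Cutoff in angstroms.
#' @return Density value(s).
#' @export
density_rho <- function(r, r_cutoff = 4.0) {
  if (any(r < 0)) rlang::abort("distance must be non-negative")
  ifelse(r <= r_cutoff, exp(-r^2 / 2), 0)
}

#' Tile origins covering a structure
#'
#' Computes the Cartesian origins of the overlapping cubic tiles that cover
#' the axis-aligned bounding box of the protein heavy atoms: per axis,
#' tiles start at the (optionally padded) box minimum and advance by
#' `stride * voxel_size` until the box maximum falls inside the last tile.
#' A structure that fits in one cube yields exactly one origin.
#'
#' @param structure A channel-typed `protein_structure`.
#' @param spec A `grid_spec`.
#' @param pad Extra padding in angstroms applied to the bounding box minimum
#'   (default 0; atoms outside a tile still contribute density within
#'   `r_cutoff` of its boundary, so no padding is needed for coverage).
#' @return A tibble with one row per tile: `ox`, `oy`, `oz`.
#' @export
tile_origins <- function(structure, spec, pad = 0) {
  p <- protein_atoms(structure)
  if (nrow(p) == 0) rlang::abort("structure has no protein atoms")
  cube_a <- spec$cube_size * spec$voxel_size
  stride_a <- spec$stride * spec$voxel_size
  axis_origins <- function(v) {
    lo <- min(v) - pad
    extent <- max(v) - lo
    k <- if (extent <= cube_a) 1L else ceiling((extent - cube_a) / stride_a) + 1L
    lo + stride_a * (seq_len(k) - 1L)
  }
  grid <- expand.grid(ox = axis_origins(p$x), oy = axis_origins(p$y),
                      oz = axis_origins(p$z), KEEP.OUT.ATTRS = FALSE)
  tibble::as_tibble(grid)
}

#' Voxelize one tile of a structure
#'
#' Builds the multi-channel density image of one cubic tile: the value at a
#' voxel and channel is the sum over that channel's atoms of the truncated
#' Gaussian density at the distance from the voxel center to the atom.
#' Voxel centers sit at `origin + (i + 0.5) * voxel_size` (0-based `i`).
#' Atoms outside the tile still contribute within `r_cutoff` of its
#' boundary. Only protein (non-hetero) atoms are imaged.
#'
#' @param structure A channel-typed `protein_structure`
#'   (see [strip_and_type_atoms()]).
#' @param origin Cartesian coordinates of the tile corner (length 3).
#' @param spec A `grid_spec`.
#' @return A `voxel_grid`: list of `values`
#'   (`cube_size^3 x n_channels` array), `origin`, `spec`.
#' @export
voxelize <- function(structure, origin, spec) {
  if (!("channels" %in% names(structure$atoms))) {
    rlang::abort("structure has no channel assignments; run strip_and_type_atoms() first")
  }
  origin <- as.numeric(origin)
  n <- spec$cube_size
  v <- spec$voxel_size
  rc <- spec$r_cutoff
  centers <- origin_axis_centers(origin, n, v)
  values <- array(0, dim = c(n, n, n, spec$n_channels))
  p <- protein_atoms(structure)
  coords <- cbind(p$x, p$y, p$z)
  chans <- p$channels
  for (a in seq_len(nrow(p))) {
    ix <- axis_window(centers$x, coords[a, 1], rc)
    iy <- axis_window(centers$y, coords[a, 2], rc)
    iz <- axis_window(centers$z, coords[a, 3], rc)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (centers$x[ix] - coords[a, 1])^2
    dy2 <- (centers$y[iy] - coords[a, 2])^2
    dz2 <- (centers$z[iz] - coords[a, 3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    dens <- exp(-d2 / 2)
    dens[d2 > rc^2] <- 0
    for (ch in chans[[a]]) {
      values[ix, iy, iz, ch] <- values[ix, iy, iz, ch] + dens
    }
  }
  structure(list(values = values, origin = origin, spec = spec),
            class = "voxel_grid")
}

origin_axis_centers <- function(origin, n, v) {
  list(x = origin[1] + (seq_len(n) - 0.5) * v,
       y = origin[2] + (seq_len(n) - 0.5) * v,
       z = origin[3] + (seq_len(n) - 0.5) * v)
}

axis_window <- function(centers, coord, rc) {
  which(abs(centers - coord) <= rc)
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d^3 x %d at origin (%.1f, %.1f, %.1f), mean density %.3g\n",
              dim(x$values)[1], dim(x$values)[4],
              x$origin[1], x$origin[2], x$origin[3], mean(x$values)))
  invisible(x)
}

#' Is a tile effectively empty?
#'
#' Tiles whose mean density over all voxels and channels falls below
#' `threshold` carry no protein and are discarded from training and
#' prediction.
#'
#' @param grid A `voxel_grid`.
#' @param threshold Mean-density threshold (default `1e-4`).
#' @return `TRUE` iff the mean density is below the threshold.
#' @export
is_empty_grid <- function(grid, threshold = 1e-4) {
  mean(grid$values) < threshold
}
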