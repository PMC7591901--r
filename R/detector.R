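#' Encode ground-truth sites as a target tensor
#'
#' For each true site center falling inside the tile, the containing
#' 8x8x8 output cell gets score 1 and the fractional position of the
#' center within that cell as its coordinate targets (the exact inverse of
#' the decoding rule). Cells are half-open, so a center exactly on a cell
#' boundary belongs to the lower-index cell. When two centers fall in one
#' cell -- which a 4-scalar cell cannot represent -- the site whose ligand
#' has more heavy atoms is kept, ties broken by lower ligand residue
#' number.
#'
#' @param sites Site tibble with `cx`, `cy`, `cz` (and optionally
#'   `n_ligand_atoms`, `ligand_resno` for conflict resolution).
#' @param tile_origin Cartesian origin of the tile (length 3).
#' @param spec A [grid_spec()] (or anything with `cube_size` and
#'   `voxel_size`).
#' @return An `8 x 8 x 8 x 4` target array (score, x, y, z).
#' @export
encode_targets <- function(sites, tile_origin, spec) {
  target <- array(0, dim = c(8, 8, 8, 4))
  if (is.null(sites) || nrow(sites) == 0) return(target)
  cell_a <- (spec$cube_size / 8) * spec$voxel_size
  if ("n_ligand_atoms" %in% names(sites)) {
    resno <- if ("ligand_resno" %in% names(sites)) sites$ligand_resno
             else seq_len(nrow(sites))
    sites <- sites[order(-sites$n_ligand_atoms, resno), , drop = FALSE]
  }
  taken <- matrix(FALSE, 0, 3)
  for (i in seq_len(nrow(sites))) {
    rel <- (c(sites$cx[i], sites$cy[i], sites$cz[i]) -
              as.numeric(tile_origin)) / cell_a
    cell <- floor(rel)
    if (any(cell < 0) || any(cell > 7)) next
    if (nrow(taken) > 0 &&
        any(taken[, 1] == cell[1] & taken[, 2] == cell[2] &
              taken[, 3] == cell[3])) next
    frac <- rel - cell
    target[cell[1] + 1, cell[2] + 1, cell[3] + 1, ] <- c(1, frac)
    taken <- rbind(taken, cell)
  }
  target
}

#' Decode a detection tensor to Cartesian predictions
#'
#' One prediction per output cell: the cell's probability score, and the
#' Cartesian center
#' `X = cell_size * voxel_size * (i_cell + x_hat) + origin_x`
#' (0-based cell indices), likewise for y and z. No thresholding happens
#' here.
#'
#' @param tensor An `8 x 8 x 8 x 4` prediction array (score, x, y, z),
#'   or a `(512) x 4` matrix in cell-major order.
#' @param tile_origin Cartesian origin of the tile.
#' @param spec A [grid_spec()] (or the model's config: needs `cube_size`
#'   and `voxel_size`).
#' @return A tibble with `i`, `j`, `k` (0-based cells), `score`, `x`,
#'   `y`, `z`.
#' @export
decode_detections <- function(tensor, tile_origin, spec) {
  M <- matrix(tensor, ncol = 4)
  cell_a <- (spec$cube_size / 8) * spec$voxel_size
  cells <- expand.grid(i = 0:7, j = 0:7, k = 0:7)
  tile_origin <- as.numeric(tile_origin)
  tibble::tibble(
    i = cells$i, j = cells$j, k = cells$k,
    score = M[, 1],
    x = cell_a * (cells$i + M[, 2]) + tile_origin[1],
    y = cell_a * (cells$j + M[, 3]) + tile_origin[2],
    z = cell_a * (cells$k + M[, 4]) + tile_origin[3]
  )
}

#' Predict binding sites on one structure
#'
#' Runs the full single-structure pipeline: strip and channel-type the
#' atoms (if not already done), tile the structure, voxelize and scan each
#' non-empty tile with the detector, decode every cell to a Cartesian
#' scored center, merge all tiles' predictions with greedy non-maximum
#' suppression, and assign the residues within 6 angstroms of each kept
#' center.
#'
#' @param structure A `protein_structure`.
#' @param model A trained `site_detector`.
#' @param params An [nms_params()].
#' @param spec Optional [grid_spec()] override (defaults to the model's).
#' @param residue_radius Residue-assignment radius, angstroms (default 6).
#' @return Tibble of predictions: `x`, `y`, `z`, `score`, `n_merged`,
#'   `residues` (list-column), `frame`.
#' @export
predict_sites <- function(structure, model, params = nms_params(),
                          spec = NULL, residue_radius = 6) {
  spec <- spec %||% model$spec
  if (!("channels" %in% names(structure$atoms))) {
    structure <- strip_and_type_atoms(structure, spec$channel_scheme)
  }
  origins <- tile_origins(structure, spec)
  raw <- purrr::map_dfr(seq_len(nrow(origins)), function(t) {
    origin <- as.numeric(origins[t, ])
    grid <- voxelize(structure, origin, spec)
    if (is_empty_grid(grid)) return(NULL)
    fwd <- model_forward(model, list(grid$values), training = FALSE)
    decode_detections(fwd$Y, origin, spec)
  })
  if (nrow(raw) == 0) {
    return(tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                          score = numeric(0), n_merged = integer(0),
                          residues = list(), frame = integer(0)))
  }
  kept <- nms(raw[, c("x", "y", "z", "score")], params)
  kept <- assign_residues(kept, structure, residue_radius)
  kept$frame <- structure$model_index
  kept
}
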