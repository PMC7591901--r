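#' Non-maximum suppression parameters
#'
#' @param s_threshold Minimum probability score kept (default 0.1; the
#'   benchmarking setting is 0.01 so average precision covers all
#'   predictions).
#' @param d_threshold Suppression radius in angstroms (default 8; use 4 to
#'   keep close orthosteric/allosteric pairs distinct).
#' @param n_top Number of kept predictions, or `Inf` for all (default `Inf`).
#' @return An `nms_params` object.
#' @export
nms_params <- function(s_threshold = 0.1, d_threshold = 8, n_top = Inf) {
  if (d_threshold <= 0) rlang::abort("d_threshold must be positive")
  structure(list(s_threshold = s_threshold, d_threshold = d_threshold,
                 n_top = n_top),
            class = "nms_params")
}

#' Greedy non-maximum suppression in Cartesian space
#'
#' Discards predictions scoring below `s_threshold`; then repeatedly takes
#' the highest-scoring remaining prediction as a cluster seed and absorbs
#' every remaining prediction whose center lies within `d_threshold` of
#' it; finally keeps the `n_top` best seeds. Kept centers are pairwise
#' more than `d_threshold` apart. Score ties are broken by lower `x`,
#' then `y`, then `z`, for determinism.
#'
#' @param preds Tibble of predictions with columns `x`, `y`, `z`, `score`
#'   (all centers in one global Cartesian frame).
#' @param params An [nms_params()].
#' @return The kept seed rows, ordered by descending score, with a
#'   `n_merged` column counting absorbed predictions (seed included).
#' @export
nms <- function(preds, params = nms_params()) {
  preds <- tibble::as_tibble(preds)
  preds <- dplyr::filter(preds, .data$score >= params$s_threshold)
  if (nrow(preds) == 0) return(dplyr::mutate(preds, n_merged = integer(0)))
  ord <- order(-preds$score, preds$x, preds$y, preds$z)
  preds <- preds[ord, , drop = FALSE]
  xyz <- as.matrix(preds[, c("x", "y", "z")])
  alive <- rep(TRUE, nrow(preds))
  keep <- integer(0)
  n_merged <- integer(0)
  while (any(alive)) {
    i <- which(alive)[1]
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    absorbed <- alive & d2 <= params$d_threshold^2
    keep <- c(keep, i)
    n_merged <- c(n_merged, sum(absorbed))
    alive <- alive & !absorbed
  }
  out <- preds[keep, , drop = FALSE]
  out$n_merged <- n_merged
  utils::head(out, if (is.finite(params$n_top)) params$n_top else nrow(out))
}

#' Assign binding-site residues to a prediction
#'
#' A residue belongs to a predicted site if at least one of its heavy
#' atoms lies within `radius` (inclusive) of the predicted center.
#'
#' @param preds Prediction tibble with `x`, `y`, `z` columns.
#' @param structure The `protein_structure` predicted on.
#' @param radius Neighborhood radius in angstroms (default 6).
#' @return `preds` with a `residues` list-column of residue ids
#'   (`chain|resno|insert`).
#' @export
assign_residues <- function(preds, structure, radius = 6) {
  p <- protein_atoms(structure)
  p <- p[!(p$element %in% c("H", "D")), , drop = FALSE]
  xyz <- cbind(p$x, p$y, p$z)
  rid <- paste(p$chain, p$resno, p$insert, sep = "|")
  preds$residues <- lapply(seq_len(nrow(preds)), function(i) {
    ctr <- c(preds$x[i], preds$y[i], preds$z[i])
    d2 <- colSums((t(xyz) - ctr)^2)
    unique(rid[d2 <= radius^2])
  })
  preds
}

#' Rotation matrix about an axis (Rodrigues formula)
#'
#' @param axis Length-3 axis vector (normalized internally).
#' @param angle Rotation angle in radians.
#' @return A 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Axes through the facet centroids of a regular icosahedron
#'
#' The 20 facet centroids of a regular icosahedron form 10 antipodal
#' pairs; each pair defines one rotation axis. Axes are unit vectors.
#'
#' @return A 10 x 3 matrix of unit axis vectors.
#' @export
icosahedron_facet_axes <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, phi), c(0, 1, -phi), c(0, -1, phi), c(0, -1, -phi),
    c(1, phi, 0), c(1, -phi, 0), c(-1, phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1)
  )
  edge <- 2
  faces <- t(utils::combn(12, 3))
  ok <- apply(faces, 1, function(f) {
    d <- stats::dist(v[f, ])
    all(abs(d - edge) < 1e-9)
  })
  cent <- t(apply(faces[ok, , drop = FALSE], 1, function(f) colMeans(v[f, ])))
  cent <- cent / sqrt(rowSums(cent^2))
  # deduplicate antipodal pairs: keep the representative with positive
  # first nonzero component
  canon <- t(apply(cent, 1, function(a) {
    s <- sign(a[which(abs(a) > 1e-9)[1]])
    round(a * s, 9)
  }))
  unique(canon)
}

#' Generate rotation replicas of a structure
#'
#' Rigidly rotates the structure about axes through its protein-atom
#' centroid along the 10 icosahedron-facet directions, by each of the
#' given angles; the default grid yields 50 replicas.
#'
#' @param structure A `protein_structure`.
#' @param axes Matrix of axis vectors (default [icosahedron_facet_axes()]).
#' @param angles Rotation angles in radians
#'   (default `pi/3, 2*pi/3, pi, 4*pi/3, 5*pi/3`).
#' @return A list of rotated structures; attribute `rotations` holds the
#'   corresponding 3x3 matrices and attribute `center` the rotation center.
#' @export
make_replicas <- function(structure, axes = icosahedron_facet_axes(),
                          angles = pi * c(1, 2, 3, 4, 5) / 3) {
  center <- structure_centroid(structure)
  rotations <- list()
  out <- list()
  k <- 0
  for (i in seq_len(nrow(axes))) {
    for (ang in angles) {
      k <- k + 1
      rot <- rotation_about_axis(axes[i, ], ang)
      rotations[[k]] <- rot
      out[[k]] <- rotate_structure(structure, rot, center)
    }
  }
  attr(out, "rotations") <- rotations
  attr(out, "center") <- center
  out
}

#' Average predictions over rotation replicas
#'
#' Maps each replica's predictions back to the reference frame by the
#' inverse rotation, pools them, groups the pool by the same greedy
#' seed-and-absorb rule as [nms()] at `d_threshold`, and replaces each
#' group by its mean center and its mean score over replicas (replicas
#' contributing nothing to a group count as zero, so a site seen in one
#' replica out of fifty is downweighted fifty-fold). Score thresholding
#' and `n_top` are applied after averaging.
#'
#' @param per_replica List of prediction tibbles (`x`, `y`, `z`, `score`),
#'   one per replica, each in its own rotated frame.
#' @param rotations List of the 3x3 rotation matrices used to build the
#'   replicas (e.g. `attr(replicas, "rotations")`).
#' @param center Rotation center used to build the replicas.
#' @param params An [nms_params()].
#' @return Tibble of averaged predictions: `x`, `y`, `z`, `score`,
#'   `n_replicas_contributing`.
#' @export
average_replica_predictions <- function(per_replica, rotations, center,
                                        params = nms_params()) {
  if (length(per_replica) != length(rotations)) {
    rlang::abort("per_replica and rotations lengths differ")
  }
  n_rep <- length(per_replica)
  pooled <- purrr::map_dfr(seq_len(n_rep), function(r) {
    pr <- tibble::as_tibble(per_replica[[r]])
    if (nrow(pr) == 0) return(pr)
    xyz <- as.matrix(pr[, c("x", "y", "z")])
    back <- sweep(sweep(xyz, 2, center) %*% rotations[[r]], 2, center,
                  FUN = "+")
    pr$x <- back[, 1]; pr$y <- back[, 2]; pr$z <- back[, 3]
    pr$replica <- r
    pr
  })
  if (nrow(pooled) == 0) {
    return(tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                          score = numeric(0),
                          n_replicas_contributing = integer(0)))
  }
  ord <- order(-pooled$score, pooled$x, pooled$y, pooled$z)
  pooled <- pooled[ord, , drop = FALSE]
  xyz <- as.matrix(pooled[, c("x", "y", "z")])
  alive <- rep(TRUE, nrow(pooled))
  groups <- list()
  while (any(alive)) {
    i <- which(alive)[1]
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    absorbed <- alive & d2 <= params$d_threshold^2
    groups[[length(groups) + 1]] <- which(absorbed)
    alive <- alive & !absorbed
  }
  out <- purrr::map_dfr(groups, function(idx) {
    g <- pooled[idx, , drop = FALSE]
    tibble::tibble(
      x = mean(g$x), y = mean(g$y), z = mean(g$z),
      score = sum(g$score) / n_rep,
      n_replicas_contributing = length(unique(g$replica))
    )
  })
  out <- dplyr::filter(out, .data$score >= params$s_threshold)
  out <- dplyr::arrange(out, dplyr::desc(.data$score))
  utils::head(out, if (is.finite(params$n_top)) params$n_top else nrow(out))
}
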