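#' Training-corpus curation policy
#'
#' Thresholds used to curate protein-ligand complexes into a training
#' corpus: crystallographic resolution better than `max_resolution`, fewer
#' than `max_chains` protein chains, chains of at least `min_chain_length`
#' residues, ligands with more than `min_ligand_heavy_atoms` heavy atoms
#' that are not detergents/buffers/cryoprotectants, binding sites with at
#' least `min_site_protein_atoms` protein heavy atoms within `site_distance`
#' of the ligand, and no principal-axis extent beyond
#' `max_principal_extent`.
#'
#' @param max_resolution Angstroms; structures must be better (strictly
#'   less) than this (default 3.0).
#' @param max_chains Exclusive chain-count bound (default 4: fewer than
#'   four chains pass).
#' @param min_chain_length Minimum residues per retained chain (default 50).
#' @param min_ligand_heavy_atoms Exclusive lower bound on ligand heavy
#'   atoms (default 14: a ligand needs more than 14).
#' @param min_site_protein_atoms Minimum protein heavy atoms in the site
#'   (default 20).
#' @param site_distance Contact distance defining the site, angstroms
#'   (default 4.0).
#' @param max_principal_extent Maximum extent along any principal axis,
#'   angstroms (default 250).
#' @param excluded_residue_names Residue names never counted as ligands;
#'   defaults to the bundled detergent/buffer/cryoprotectant list.
#' @return A `curation_policy` object.
#' @export
curation_policy <- function(max_resolution = 3.0, max_chains = 4L,
                            min_chain_length = 50L,
                            min_ligand_heavy_atoms = 14L,
                            min_site_protein_atoms = 20L,
                            site_distance = 4.0,
                            max_principal_extent = 250,
                            excluded_residue_names = excluded_ligand_names()) {
  structure(
    list(max_resolution = max_resolution, max_chains = as.integer(max_chains),
         min_chain_length = as.integer(min_chain_length),
         min_ligand_heavy_atoms = as.integer(min_ligand_heavy_atoms),
         min_site_protein_atoms = as.integer(min_site_protein_atoms),
         site_distance = site_distance,
         max_principal_extent = max_principal_extent,
         excluded_residue_names = excluded_residue_names),
    class = "curation_policy"
  )
}

#' Bundled detergent/buffer/cryoprotectant exclusion list
#'
#' Residue names of common crystallization additives that must not count
#' as ligands. Read from `inst/extdata/excluded_ligands.txt`; users can
#' extend the list by passing extra names to [curation_policy()].
#'
#' @return Character vector of 3-letter residue names.
#' @export
excluded_ligand_names <- function() {
  path <- system.file("extdata", "excluded_ligands.txt", package = "voxsite")
  if (path == "") path <- file.path("inst", "extdata", "excluded_ligands.txt")
  out <- readLines(path, warn = FALSE)
  out <- trimws(sub("#.*$", "", out))
  out[out != ""]
}

#' Extract candidate ligands from a structure
#'
#' Keeps hetero groups with strictly more than the policy's heavy-atom
#' minimum (hydrogens never counted) whose residue name is not on the
#' exclusion list. Waters and monoatomic ions fail the size bound
#' automatically.
#'
#' @param structure A `protein_structure`.
#' @param policy A `curation_policy`.
#' @return A list of ligand atom tibbles.
#' @export
extract_ligands <- function(structure, policy = curation_policy()) {
  groups <- hetero_groups(structure)
  keep <- vapply(groups, function(g) {
    heavy <- sum(!(g$element %in% c("H", "D")))
    heavy > policy$min_ligand_heavy_atoms &&
      !(g$resname[1] %in% policy$excluded_residue_names)
  }, logical(1))
  groups[keep]
}

#' Ground-truth binding site for one ligand
#'
#' The site comprises the protein heavy atoms within `site_distance` of
#' any ligand heavy atom; the site center is the center of mass (heavy
#' atoms weighted equally) of the full residues contributing those atoms.
#'
#' @param structure A `protein_structure`.
#' @param ligand One ligand atom tibble (e.g. from [extract_ligands()]).
#' @param site_distance Contact distance in angstroms (default 4.0).
#' @return One-row tibble: `site_id`, `ligand_resname`, `ligand_chain`,
#'   `ligand_resno`, `n_ligand_atoms`, `n_site_atoms`, `cx`, `cy`, `cz`,
#'   `residues` (list-column of site residue ids `chain|resno|insert`).
#' @export
binding_site_from_ligand <- function(structure, ligand, site_distance = 4.0) {
  p <- protein_atoms(structure)
  p <- p[!(p$element %in% c("H", "D")), , drop = FALSE]
  lig <- ligand[!(ligand$element %in% c("H", "D")), , drop = FALSE]
  dmin <- min_dist_to_set(cbind(p$x, p$y, p$z), cbind(lig$x, lig$y, lig$z))
  contact <- dmin <= site_distance
  resid <- paste(p$chain, p$resno, p$insert, sep = "|")
  site_res <- unique(resid[contact])
  res_atoms <- p[resid %in% site_res, , drop = FALSE]
  ctr <- if (nrow(res_atoms) > 0) {
    c(mean(res_atoms$x), mean(res_atoms$y), mean(res_atoms$z))
  } else c(NA_real_, NA_real_, NA_real_)
  tibble::tibble(
    site_id = paste(ligand$chain[1], ligand$resno[1], ligand$resname[1],
                    sep = "|"),
    ligand_resname = ligand$resname[1],
    ligand_chain = ligand$chain[1],
    ligand_resno = ligand$resno[1],
    n_ligand_atoms = nrow(lig),
    n_site_atoms = sum(contact),
    cx = ctr[1], cy = ctr[2], cz = ctr[3],
    residues = list(site_res)
  )
}

# row-wise minimum Euclidean distance from points to a reference set
min_dist_to_set <- function(points, ref) {
  if (nrow(ref) == 0) return(rep(Inf, nrow(points)))
  pr <- rowSums(points^2)
  rr <- rowSums(ref^2)
  d2 <- outer(pr, rr, "+") - 2 * points %*% t(ref)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Accept or reject a ligand's binding site
#'
#' A site is accepted iff at least the policy's minimum number of protein
#' heavy atoms lie within `site_distance` of any ligand heavy atom.
#'
#' @inheritParams binding_site_from_ligand
#' @param policy A `curation_policy`.
#' @return A list: `accepted` flag and `site` (the [binding_site_from_ligand()]
#'   row).
#' @export
accept_site <- function(structure, ligand, policy = curation_policy()) {
  site <- binding_site_from_ligand(structure, ligand, policy$site_distance)
  list(accepted = site$n_site_atoms >= policy$min_site_protein_atoms,
       site = site)
}

#' Structure-level curation filters
#'
#' Applies resolution, chain-count, chain-length, and principal-extent
#' filters. Chains shorter than the minimum length are dropped (not the
#' whole structure); the structure is rejected if its resolution is not
#' better than the cutoff, it has too many chains, nothing remains after
#' chain dropping, or any principal-axis extent (range of heavy-atom
#' coordinates projected on the principal components of the coordinate
#' covariance) exceeds the maximum.
#'
#' @param structure A `protein_structure`.
#' @param metadata Optional list/row with `resolution` (angstroms) and
#'   optionally `n_chains`; a missing resolution skips that filter with a
#'   warning.
#' @param policy A `curation_policy`.
#' @return A list: `accepted` flag, `structure` (with short chains
#'   dropped), `reasons` (character vector of failed filters).
#' @export
structure_filters <- function(structure, metadata = NULL,
                              policy = curation_policy()) {
  reasons <- character(0)
  if (is.null(metadata) || is.null(metadata$resolution) ||
      is.na(metadata$resolution)) {
    rlang::warn("resolution metadata missing; resolution filter skipped")
  } else if (metadata$resolution >= policy$max_resolution) {
    reasons <- c(reasons, "resolution")
  }
  p <- protein_atoms(structure)
  n_chains <- length(unique(p$chain))
  if (n_chains >= policy$max_chains) reasons <- c(reasons, "chain_count")
  # drop short chains
  chain_len <- p |>
    dplyr::distinct(.data$chain, .data$resno, .data$insert) |>
    dplyr::count(.data$chain)
  short <- chain_len$chain[chain_len$n < policy$min_chain_length]
  atoms <- structure$atoms
  atoms <- atoms[!(atoms$chain %in% short & !atoms$hetero), , drop = FALSE]
  if (sum(!atoms$hetero) == 0) {
    reasons <- c(reasons, "no_chains_left")
    return(list(accepted = FALSE, structure = NULL, reasons = reasons))
  }
  kept <- protein_structure(atoms, structure$model_index)
  ext <- principal_extents(kept)
  if (any(ext > policy$max_principal_extent)) {
    reasons <- c(reasons, "principal_extent")
  }
  list(accepted = length(reasons) == 0, structure = kept, reasons = reasons)
}

#' Principal-axis extents of the protein heavy atoms
#'
#' Extent = max minus min of coordinates projected on each principal
#' component of the coordinate covariance.
#'
#' @param structure A `protein_structure`.
#' @return Numeric vector of three extents, angstroms.
#' @export
principal_extents <- function(structure) {
  p <- protein_atoms(structure)
  p <- p[!(p$element %in% c("H", "D")), , drop = FALSE]
  xyz <- cbind(p$x, p$y, p$z)
  pc <- stats::prcomp(xyz, center = TRUE, scale. = FALSE)
  apply(pc$x, 2, function(v) diff(range(v)))
}

#' Similarity-aware train/validation split
#'
#' Groups chains so that the structural similarity of any two chains from
#' different groups is below `threshold` (single-linkage agglomeration of
#' the similarity graph, i.e. connected components under
#' `similarity >= threshold`), then assigns whole groups to the validation
#' side until its target fraction is approached. No train/validation pair
#' can share similarity at or above the threshold.
#'
#' @param sim A symmetric similarity matrix with unit diagonal and row/col
#'   names identifying chains (values in `[0, 1]`, e.g. TM-scores computed
#'   externally).
#' @param threshold Similarity threshold (default 0.5).
#' @param val_fraction Target fraction of chains in the validation set.
#' @return A list: `train` and `val` character vectors of chain ids, and
#'   `clusters` (integer cluster id per chain).
#' @export
split_train_val <- function(sim, threshold = 0.5, val_fraction = 0.2) {
  if (!isTRUE(all.equal(sim, t(sim), tolerance = 1e-8))) {
    rlang::abort("similarity matrix must be symmetric")
  }
  ids <- rownames(sim)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(sim)))
  n <- nrow(sim)
  if (n == 1) return(list(train = ids, val = character(0), clusters = 1L))
  d <- stats::as.dist(1 - sim)
  hc <- stats::hclust(d, method = "single")
  cl <- stats::cutree(hc, h = 1 - threshold)
  names(cl) <- ids
  sizes <- sort(table(cl), decreasing = TRUE)
  target <- val_fraction * n
  val_clusters <- integer(0)
  n_val <- 0
  for (cid in as.integer(names(sizes))) {
    sz <- sizes[[as.character(cid)]]
    if (sz > (1 - val_fraction) * n) {
      rlang::warn("a similarity cluster exceeds the training fraction; assigned to train")
      next
    }
    if (n_val + sz <= ceiling(target)) {
      val_clusters <- c(val_clusters, cid)
      n_val <- n_val + sz
    }
    if (n_val >= floor(target)) break
  }
  val <- ids[cl %in% val_clusters]
  list(train = setdiff(ids, val), val = val, clusters = cl)
}

#' Count atoms displaced between two versions of a structure
#'
#' Generic refinement-impact predicate: given the same structure before and
#' after coordinate refinement, counts site atoms whose position moved by
#' more than `tol`; complexes where three or more binding-site atoms moved
#' are conventionally discarded.
#'
#' @param before,after Two `protein_structure` objects with identical atom
#'   ordering.
#' @param site_residues Character vector of residue ids (`chain|resno|insert`)
#'   restricting the count to the binding site; `NULL` counts all atoms.
#' @param tol Displacement tolerance, angstroms (default 0.1).
#' @return Integer count of displaced atoms.
#' @export
count_displaced_atoms <- function(before, after, site_residues = NULL,
                                  tol = 0.1) {
  a <- before$atoms; b <- after$atoms
  if (nrow(a) != nrow(b)) rlang::abort("structures differ in atom count")
  d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  if (!is.null(site_residues)) {
    rid <- paste(a$chain, a$resno, a$insert, sep = "|")
    d <- d[rid %in% site_residues]
  }
  sum(d > tol)
}
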