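#' Protein structure objects
#'
#' A `protein_structure` wraps a tibble of atom records (one row per atom)
#' plus the ensemble frame it came from. Protein atoms (`hetero = FALSE`)
#' are the object that gets imaged; HETATM groups ride along as candidate
#' ligands for ground-truth definition and curation.
#'
#' @param atoms A data frame with columns `element`, `name` (PDB atom name),
#'   `x`, `y`, `z` (Cartesian angstroms), `resname`, `chain`, `resno`,
#'   `insert`, `hetero`, `occupancy`, `altloc`.
#' @param model_index Ensemble frame number (1-based).
#' @return An object of class `protein_structure`.
#' @export
protein_structure <- function(atoms, model_index = 1L) {
  atoms <- tibble::as_tibble(atoms)
  needed <- c("element", "name", "x", "y", "z", "resname", "chain",
              "resno", "insert", "hetero", "occupancy", "altloc")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("atoms is missing columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    rlang::abort("atom coordinates must be finite")
  }
  structure(
    list(atoms = atoms, model_index = as.integer(model_index)),
    class = "protein_structure"
  )
}

#' @export
print.protein_structure <- function(x, ...) {
  np <- sum(!x$atoms$hetero)
  nh <- sum(x$atoms$hetero)
  cat(sprintf(
    "<protein_structure> frame %d: %d protein atoms, %d hetero atoms, %d chains\n",
    x$model_index, np, nh, length(unique(x$atoms$chain[!x$atoms$hetero]))
  ))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.protein_structure <- function(x, ...) x$atoms

protein_atoms <- function(structure) {
  dplyr::filter(structure$atoms, !.data$hetero)
}

#' Hetero-group atom tables of a structure
#'
#' Splits HETATM records into groups by (chain, residue number, insertion
#' code, residue name); each group is one candidate ligand or solvent
#' molecule.
#'
#' @param structure A `protein_structure`.
#' @return A list of atom tibbles, one per hetero group.
#' @export
hetero_groups <- function(structure) {
  het <- dplyr::filter(structure$atoms, .data$hetero)
  if (nrow(het) == 0) return(list())
  key <- paste(het$chain, het$resno, het$insert, het$resname, sep = "|")
  unname(split(het, factor(key, levels = unique(key))))
}

.WATER_NAMES <- c("HOH", "DOD", "WAT", "H2O", "TIP", "TIP3", "SOL")

#' Read protein structures from a PDB file
#'
#' Parses ATOM/HETATM records via \pkg{bio3d}; multi-model files (MODEL /
#' ENDMDL) yield one `protein_structure` per model with `model_index` set.
#'
#' @param path Path to a PDB file.
#' @return A list of `protein_structure` objects (length 1 for single-model
#'   files).
#' @export
read_structures <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  element <- toupper(trimws(a$elesy))
  bad <- is.na(element) | element == ""
  if (any(bad)) {
    # fall back to the first alphabetic character of the atom name
    guess <- toupper(substr(gsub("[^A-Za-z].*$", "",
                                 sub("^[0-9]*", "", trimws(a$elety[bad]))), 1, 1))
    element[bad] <- guess
  }
  base <- tibble::tibble(
    element = element,
    name = trimws(a$elety),
    resname = trimws(a$resid),
    chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    resno = as.integer(a$resno),
    insert = ifelse(is.na(a$insert), "", a$insert),
    hetero = a$type == "HETATM",
    occupancy = ifelse(is.na(a$o), 1, a$o),
    altloc = ifelse(is.na(a$alt), "", a$alt)
  )
  n_models <- nrow(pdb$xyz)
  lapply(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    atoms <- dplyr::mutate(base, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                           .after = "name")
    protein_structure(atoms, model_index = m)
  })
}

#' Strip non-imaged atoms and assign density channels
#'
#' Removes hydrogens/deuteriums, water molecules, and monoatomic ions;
#' resolves alternate locations by keeping the highest-occupancy altloc
#' (ties broken by altloc letter order); and maps every remaining protein
#' heavy atom to one or more density channels of the chosen scheme.
#' Hetero (ligand) atoms are kept for ground-truth purposes but carry no
#' channels and are never imaged.
#'
#' @param structure A `protein_structure`.
#' @param channel_scheme Name of a registered channel scheme
#'   (`"default"`, 11 channels, or `"minimal"`, 4 channels).
#' @return The structure with a `channels` list-column on its atom table
#'   (integer channel indices per atom; `NULL` entries for hetero atoms)
#'   and the scheme name recorded as attribute `channel_scheme`.
#' @export
strip_and_type_atoms <- function(structure, channel_scheme = "default") {
  atoms <- structure$atoms
  atoms <- dplyr::filter(atoms, !(.data$element %in% c("H", "D")))
  atoms <- dplyr::filter(atoms, !(.data$resname %in% .WATER_NAMES))
  # monoatomic hetero groups are ions
  if (any(atoms$hetero)) {
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resname, sep = "|")
    grp_n <- stats::ave(seq_along(key), key, FUN = length)
    atoms <- atoms[!(atoms$hetero & grp_n == 1), , drop = FALSE]
  }
  # altloc: highest occupancy wins, then altloc letter order
  if (any(atoms$altloc != "")) {
    atoms <- atoms |>
      dplyr::group_by(.data$chain, .data$resno, .data$insert,
                      .data$resname, .data$name) |>
      dplyr::arrange(dplyr::desc(.data$occupancy), .data$altloc,
                     .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
  }
  if (sum(!atoms$hetero) == 0) rlang::abort("empty structure after stripping")
  scheme <- get_channel_scheme(channel_scheme)
  ch <- vector("list", nrow(atoms))
  prot <- !atoms$hetero
  ch[prot] <- scheme$assign(atoms[prot, , drop = FALSE])
  atoms$channels <- ch
  out <- protein_structure(atoms, structure$model_index)
  attr(out, "channel_scheme") <- channel_scheme
  out
}

#' Rigidly rotate a structure about a point
#'
#' @param structure A `protein_structure`.
#' @param rotation A 3x3 rotation matrix.
#' @param center Point to rotate about; defaults to the centroid of the
#'   protein heavy atoms.
#' @return The rotated structure (all atoms, ligands included, move rigidly).
#' @export
rotate_structure <- function(structure, rotation, center = NULL) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)))
  if (is.null(center)) center <- structure_centroid(structure)
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, center) %*% t(rotation)
  xyz <- sweep(xyz, 2, center, FUN = "+")
  atoms <- structure$atoms
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  out <- protein_structure(atoms, structure$model_index)
  attributes(out)[setdiff(names(attributes(structure)),
                          c("names", "class"))] <-
    attributes(structure)[setdiff(names(attributes(structure)),
                                  c("names", "class"))]
  out
}

structure_centroid <- function(structure) {
  p <- protein_atoms(structure)
  c(mean(p$x), mean(p$y), mean(p$z))
}
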