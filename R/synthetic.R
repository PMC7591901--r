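#' Specification for synthetic planted-pocket structures
#'
#' Synthetic fixtures emulate compact globular proteins: a heavy-atom cloud
#' organized into residues and chains, with one or more concave pockets
#' carved into the surface, a multi-atom ligand planted inside each pocket,
#' and a lining shell of residues guaranteeing the ligand makes enough
#' protein contacts to pass curation. They are valid input to every stage
#' of the pipeline, including training.
#'
#' @param n_residues Number of pseudo-residues in the globule (default 60;
#'   must exceed the 50-residue minimum chain length used in curation).
#' @param pocket_count Pockets per structure (default 1).
#' @param pocket_radius Radius of the carved pocket, angstroms (default 4.5).
#' @param ligand_heavy_atoms Heavy atoms per planted ligand (default 16;
#'   must exceed 14 to pass the ligand-size curation filter).
#' @param box_extent Approximate globule diameter, angstroms (default 22).
#' @param noise_scale Coordinate jitter applied to atom placement, angstroms
#'   (default 0.3).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(n_residues = 60L, pocket_count = 1L,
                         pocket_radius = 4.5, ligand_heavy_atoms = 16L,
                         box_extent = 22, noise_scale = 0.3, seed = 1L) {
  if (ligand_heavy_atoms <= 14) {
    rlang::abort("ligand_heavy_atoms must exceed 14 so fixtures pass curation")
  }
  if (pocket_radius * 2 >= box_extent) {
    rlang::abort("infeasible geometry: pocket larger than structure")
  }
  structure(
    list(n_residues = as.integer(n_residues),
         pocket_count = as.integer(pocket_count),
         pocket_radius = pocket_radius,
         ligand_heavy_atoms = as.integer(ligand_heavy_atoms),
         box_extent = box_extent, noise_scale = noise_scale,
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

.FIXTURE_RESNAMES <- c("ALA", "LEU", "SER", "VAL", "THR", "ILE",
                       "PHE", "ASP", "LYS", "GLY")

# one pseudo-residue: backbone N, CA, O plus side-chain CB around a center
.residue_atoms <- function(center, resno, resname, chain, noise) {
  offs <- rbind(
    N  = c(-1.46, 0, 0),
    CA = c(0, 0, 0),
    CB = c(0.75, 1.3, 0),
    O  = c(1.2, -0.8, 0.4)
  )
  rot <- .random_rotation()
  pos <- sweep(offs %*% t(rot), 2, center, FUN = "+") +
    matrix(stats::rnorm(12, sd = noise), 4, 3)
  dimnames(pos) <- NULL
  tibble::tibble(
    element = c("N", "C", "C", "O"),
    name = c("N", "CA", "CB", "O"),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    resname = resname, chain = chain, resno = as.integer(resno),
    insert = "", hetero = FALSE, occupancy = 1, altloc = ""
  )
}

.random_unit <- function(n = 1) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

.random_rotation <- function() {
  axis <- as.numeric(.random_unit())
  rotation_about_axis(axis, stats::runif(1, 0, 2 * pi))
}

#' Generate a synthetic structure with planted binding sites
#'
#' Builds a compact globule of pseudo-residues, carves `pocket_count`
#' concave pockets, rings each with a lining shell of residues, and places
#' a ligand inside. Ground truth is computed by the same rules curation
#' uses: site atoms are protein heavy atoms within 4 angstroms of the
#' ligand, and the site center is the center of mass of the site residues.
#' Output is deterministic under the spec's seed.
#'
#' @param spec A `fixture_spec`.
#' @return A list with `structure` (a `protein_structure`) and `sites`
#'   (a tibble: `site_id`, ligand identity, `cx`, `cy`, `cz`,
#'   `n_site_atoms`, `n_ligand_atoms`, `residues` list-column).
#' @export
generate_structure <- function(spec) {
  # a rare unlucky draw can leave a site short of contacts; retry with
  # derived sub-seeds so output stays deterministic under the spec seed
  for (attempt in 0:19) {
    out <- withr::with_seed(spec$seed + 1000L * attempt,
                            .generate_structure_impl(spec))
    ok <- nrow(out$sites) == spec$pocket_count &&
      all(out$sites$n_site_atoms >= 20) &&
      all(out$sites$n_ligand_atoms > 14)
    if (ok) return(out)
  }
  rlang::abort("could not generate an acceptable fixture; relax the spec")
}

.generate_structure_impl <- function(spec) {
  R <- spec$box_extent / 2
  n_res <- spec$n_residues
  # pocket centers on a shell inside the globule, well separated
  pocket_dirs <- .random_unit(spec$pocket_count)
  if (spec$pocket_count > 1) {
    # spread pockets to opposite sides
    for (i in 2:spec$pocket_count) {
      while (min(colSums(t(pocket_dirs[seq_len(i - 1), , drop = FALSE]) *
                           pocket_dirs[i, ])) > 0) {
        pocket_dirs[i, ] <- .random_unit()
      }
    }
  }
  pocket_centers <- pocket_dirs * (R * 0.55)

  # globule residues: rejection-sampled centers with minimum spacing,
  # kept clear of the pockets
  centers <- matrix(NA_real_, 0, 3)
  tries <- 0
  while (nrow(centers) < n_res && tries < 20000) {
    tries <- tries + 1
    p <- .random_unit() * (R - 1.2) * stats::runif(1)^(1 / 3)
    if (nrow(centers) > 0 &&
        min(sqrt(colSums((t(centers) - as.numeric(p))^2))) < 3.1) next
    dp <- sqrt(rowSums(sweep(pocket_centers, 2, as.numeric(p))^2))
    if (min(dp) < spec$pocket_radius + 1.2) next
    centers <- rbind(centers, p)
  }
  # lining shell: residues ringing each pocket mouth so the ligand has
  # guaranteed protein contacts
  n_line <- 16L
  for (k in seq_len(spec$pocket_count)) {
    shell_dirs <- .random_unit(n_line * 3)
    d <- sqrt(rowSums(sweep(shell_dirs * (spec$pocket_radius + 0.5), 2,
                            -pocket_centers[k, ])^2))
    keep <- order(d)[seq_len(n_line)]  # prefer the inward-facing hemisphere
    shell <- sweep(shell_dirs[keep, , drop = FALSE] *
                     (spec$pocket_radius + 0.5), 2,
                   pocket_centers[k, ], FUN = "+")
    centers <- rbind(centers, shell)
  }
  n_total <- nrow(centers)
  resnames <- sample(.FIXTURE_RESNAMES, n_total, replace = TRUE)
  prot <- purrr::map_dfr(seq_len(n_total), function(i) {
    .residue_atoms(centers[i, ], i, resnames[i], "A", spec$noise_scale)
  })

  # ligands: compact random walks inside each pocket
  lig <- purrr::map_dfr(seq_len(spec$pocket_count), function(k) {
    n_l <- spec$ligand_heavy_atoms
    pos <- matrix(NA_real_, n_l, 3)
    pos[1, ] <- pocket_centers[k, ]
    for (i in 2:n_l) {
      repeat {
        cand <- pos[i - 1, ] + as.numeric(.random_unit()) * 1.5
        if (sqrt(sum((cand - pocket_centers[k, ])^2)) <=
            spec$pocket_radius - 0.8) break
      }
      pos[i, ] <- cand
    }
    tibble::tibble(
      element = sample(c(rep("C", n_l - 4), "N", "N", "O", "O")),
      name = paste0(c(rep("C", n_l - 4), "N", "N", "O", "O"),
                    seq_len(n_l)),
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      resname = "LIG", chain = "L", resno = as.integer(900 + k),
      insert = "", hetero = TRUE, occupancy = 1, altloc = ""
    )
  })

  st <- protein_structure(dplyr::bind_rows(prot, lig))
  sites <- purrr::map_dfr(hetero_groups(st), function(g) {
    binding_site_from_ligand(st, g)
  })
  list(structure = st, sites = sites)
}

#' Generate a synthetic conformational ensemble
#'
#' Perturbs a base planted-pocket structure with bounded random
#' displacements per frame; optionally the pocket (and its ligand) exists
#' only within a window of frames, giving trajectory clustering a
#' time-varying signal: outside the window the pocket is filled by plug
#' residues.
#'
#' @param spec A `fixture_spec`.
#' @param n_frames Number of frames (>= 1).
#' @param drift Bound on the per-atom displacement between consecutive
#'   frames, angstroms (0 gives identical frames).
#' @param pocket_window Optional integer vector of frames in which the
#'   pocket is open; `NULL` means always open.
#' @return A list of `protein_structure` frames; attribute `sites` holds
#'   the ground-truth site table of the open conformation and attribute
#'   `pocket_window` the window used.
#' @export
generate_trajectory <- function(spec, n_frames, drift = 0.2,
                                pocket_window = NULL) {
  if (n_frames < 1) rlang::abort("n_frames must be >= 1")
  base <- generate_structure(spec)
  open_atoms <- base$structure$atoms
  closed_atoms <- withr::with_seed(spec$seed + 7L, {
    # plug the pocket: drop the ligand, add residues at the pocket interior
    lig <- dplyr::filter(open_atoms, .data$hetero)
    plugs <- purrr::map_dfr(unique(lig$resno), function(rn) {
      g <- dplyr::filter(lig, .data$resno == rn)
      ctr <- c(mean(g$x), mean(g$y), mean(g$z))
      dplyr::bind_rows(
        .residue_atoms(ctr, max(open_atoms$resno) + 1L, "ALA", "A", 0.2),
        .residue_atoms(ctr + c(1.8, 0, 0), max(open_atoms$resno) + 2L,
                       "VAL", "A", 0.2)
      )
    })
    dplyr::bind_rows(dplyr::filter(open_atoms, !.data$hetero), plugs)
  })
  frames <- withr::with_seed(spec$seed + 13L, {
    lapply(seq_len(n_frames), function(f) {
      open <- is.null(pocket_window) || f %in% pocket_window
      atoms <- if (open) open_atoms else closed_atoms
      if (drift > 0) {
        n <- nrow(atoms)
        disp <- .random_unit(n) * stats::runif(n, 0, drift / 2)
        atoms$x <- atoms$x + disp[, 1]
        atoms$y <- atoms$y + disp[, 2]
        atoms$z <- atoms$z + disp[, 3]
      }
      protein_structure(atoms, model_index = f)
    })
  })
  attr(frames, "sites") <- base$sites
  attr(frames, "pocket_window") <- pocket_window
  frames
}

#' Write structures as PDB text
#'
#' Fixed-column PDB output; a list of structures is written as a
#' multi-model file with MODEL/ENDMDL records. Ligand (hetero) atoms are
#' emitted as HETATM. Coordinates round-trip through [read_structures()]
#' at PDB precision (1e-3 angstroms).
#'
#' @param structures A `protein_structure` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structures, path) {
  if (inherits(structures, "protein_structure")) structures <- list(structures)
  multi <- length(structures) > 1
  lines <- character(0)
  for (m in seq_along(structures)) {
    at <- structures[[m]]$atoms
    if (any(at$x <= -1000 | at$x >= 10000 | at$y <= -1000 | at$y >= 10000 |
              at$z <= -1000 | at$z >= 10000)) {
      rlang::abort("coordinates outside PDB column range")
    }
    if (multi) lines <- c(lines, sprintf("MODEL %8d", m))
    nm <- ifelse(nchar(at$name) <= 3, paste0(" ", at$name), at$name)
    rec <- sprintf(
      "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ifelse(at$hetero, "HETATM", "ATOM"),
      seq_len(nrow(at)) %% 100000L, nm, at$altloc, at$resname, at$chain,
      at$resno, at$insert, at$x, at$y, at$z, at$occupancy, 0, at$element
    )
    lines <- c(lines, rec, if (multi) "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
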