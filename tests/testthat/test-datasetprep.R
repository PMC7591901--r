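# a hetero group of n heavy atoms at the given center
ligand_atoms <- function(n, center = c(0, 0, 0), resname = "LIG",
                         resno = 900L) {
  tibble::tibble(
    element = "C", name = paste0("C", seq_len(n)),
    x = center[1] + runif(n, -1, 1), y = center[2] + runif(n, -1, 1),
    z = center[3] + runif(n, -1, 1),
    resname = resname, chain = "L", resno = resno, insert = "",
    hetero = TRUE, occupancy = 1, altloc = ""
  )
}

test_that("ligand extraction enforces the heavy-atom bound and exclusion list", {
  set.seed(1)
  prot <- make_structure(matrix(runif(30, 0, 10), 10, 3))$atoms
  st14 <- protein_structure(dplyr::bind_rows(prot, ligand_atoms(14)))
  st15 <- protein_structure(dplyr::bind_rows(prot, ligand_atoms(15)))
  gol <- protein_structure(dplyr::bind_rows(
    prot, ligand_atoms(20, resname = "GOL")))
  expect_length(extract_ligands(st14), 0)    # 14 atoms: strictly too few
  expect_length(extract_ligands(st15), 1)    # 15 atoms: accepted
  expect_length(extract_ligands(gol), 0)     # glycerol is excluded at any size
  # hydrogens never count toward the bound
  lig_h <- dplyr::bind_rows(ligand_atoms(14),
                            dplyr::mutate(ligand_atoms(5, resno = 900L),
                                          element = "H"))
  st_h <- protein_structure(dplyr::bind_rows(prot, lig_h))
  expect_length(extract_ligands(st_h), 0)
})

test_that("site acceptance needs 20 protein heavy atoms within 4 angstroms", {
  build_case <- function(n_contacts) {
    lig <- ligand_atoms(16, center = c(0, 0, 0))
    # contacts ring the ligand at 2.5 A from its first atom; spectators sit
    # far away so only the ring can satisfy the 4 A rule
    angles <- seq(0, 2 * pi, length.out = n_contacts + 1)[-1]
    contacts <- cbind(lig$x[1] + 2.5 * cos(angles),
                      lig$y[1] + 2.5 * sin(angles), lig$z[1])
    far <- matrix(100 + runif(60, 0, 10), 20, 3)
    prot <- make_structure(rbind(contacts, far))$atoms
    protein_structure(dplyr::bind_rows(prot, lig))
  }
  set.seed(2)
  st19 <- build_case(19)
  st20 <- build_case(20)
  res19 <- accept_site(st19, hetero_groups(st19)[[1]])
  res20 <- accept_site(st20, hetero_groups(st20)[[1]])
  expect_false(res19$accepted)
  expect_true(res20$accepted)
  expect_equal(res20$site$n_site_atoms, 20)
  # the site center is the brute-force center of mass of the site residues
  at <- dplyr::filter(st20$atoms, !hetero)
  lig <- hetero_groups(st20)[[1]]
  dmin <- vapply(seq_len(nrow(at)), function(i)
    min(sqrt((lig$x - at$x[i])^2 + (lig$y - at$y[i])^2 +
               (lig$z - at$z[i])^2)), numeric(1))
  rid <- paste(at$chain, at$resno, at$insert, sep = "|")
  site_res <- unique(rid[dmin <= 4])
  com <- colMeans(as.matrix(at[rid %in% site_res, c("x", "y", "z")]))
  expect_equal(c(res20$site$cx, res20$site$cy, res20$site$cz),
               unname(com))
})

test_that("structure filters drop short chains and overlong structures", {
  set.seed(3)
  # chain A: 49 residues (dropped); chain B: 60 residues (kept)
  mk_chain <- function(chain_id, n_res, offset) {
    purrr::map_dfr(seq_len(n_res), function(r) {
      at <- make_structure(matrix(runif(12, 0, 30), 4, 3))$atoms
      at$chain <- chain_id
      at$resno <- as.integer(r)
      at$x <- at$x + offset
      at
    })
  }
  st <- protein_structure(dplyr::bind_rows(mk_chain("A", 49, 0),
                                           mk_chain("B", 60, 40)))
  out <- structure_filters(st, metadata = list(resolution = 2.0))
  expect_true(out$accepted)
  expect_false("A" %in% out$structure$atoms$chain)
  expect_true("B" %in% out$structure$atoms$chain)

  # a 260 A rod fails the principal-extent filter
  rod <- make_structure(cbind(seq(0, 260, length.out = 300),
                              runif(300, 0, 10), runif(300, 0, 10)),
                        resno = rep(1:75, each = 4))
  expect_gt(max(principal_extents(rod)), 250)
  out_rod <- structure_filters(rod, metadata = list(resolution = 2.0),
                               policy = curation_policy(min_chain_length = 10))
  expect_false(out_rod$accepted)
  expect_true("principal_extent" %in% out_rod$reasons)

  # a compact 40 A globule passes
  glob <- make_structure(matrix(runif(600, 0, 40), 200, 3),
                         resno = rep(1:50, each = 4))
  out_glob <- structure_filters(glob, metadata = list(resolution = 2.0))
  expect_true(out_glob$accepted)

  # resolution not better than 3.0 A fails; missing metadata only warns
  out_res <- structure_filters(glob, metadata = list(resolution = 3.0))
  expect_false(out_res$accepted)
  expect_warning(structure_filters(glob), "resolution")

  # four chains are too many
  four <- protein_structure(purrr::map_dfr(c("A", "B", "C", "D"),
                                           mk_chain, n_res = 50,
                                           offset = 0))
  out_four <- structure_filters(four, metadata = list(resolution = 2.0))
  expect_false(out_four$accepted)
  expect_true("chain_count" %in% out_four$reasons)
})

test_that("the train/validation split never crosses the similarity threshold", {
  # two perfect blocks: one block per side at 50/50
  blocks <- matrix(0.1, 8, 8)
  blocks[1:4, 1:4] <- 0.9
  blocks[5:8, 5:8] <- 0.9
  diag(blocks) <- 1
  rownames(blocks) <- colnames(blocks) <- paste0("c", 1:8)
  sp <- split_train_val(blocks, threshold = 0.5, val_fraction = 0.5)
  expect_setequal(c(sp$train, sp$val), rownames(blocks))
  expect_length(sp$val, 4)
  expect_length(unique(sp$clusters[sp$val]), 1)

  # all-dissimilar chains split as singletons near the target fraction
  eye <- diag(10)
  rownames(eye) <- colnames(eye) <- paste0("s", 1:10)
  sp2 <- split_train_val(eye, threshold = 0.5, val_fraction = 0.3)
  expect_length(sp2$val, 3)

  # soundness: exhaustive check over random matrices
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(6:15, 1)
    sim <- matrix(runif(n * n), n, n)
    sim <- (sim + t(sim)) / 2
    diag(sim) <- 1
    rownames(sim) <- colnames(sim) <- paste0("x", seq_len(n))
    sp3 <- suppressWarnings(
      split_train_val(sim, threshold = 0.5, val_fraction = 0.3))
    if (length(sp3$val) > 0 && length(sp3$train) > 0) {
      cross <- sim[sp3$train, sp3$val, drop = FALSE]
      expect_lt(max(cross), 0.5)
    }
  }
})

test_that("an oversized similarity cluster is forced into training", {
  big <- matrix(0.9, 9, 9)
  big[9, ] <- big[, 9] <- 0.1
  diag(big) <- 1
  rownames(big) <- colnames(big) <- paste0("c", 1:9)
  expect_warning(sp <- split_train_val(big, 0.5, val_fraction = 0.3),
                 "train")
  expect_true(all(paste0("c", 1:8) %in% sp$train))
})

test_that("coordinate-displacement counting supports refinement filtering", {
  set.seed(4)
  before <- make_structure(matrix(runif(30, 0, 10), 10, 3),
                           resno = rep(1:5, each = 2))
  after <- before
  after$atoms$x[1:3] <- after$atoms$x[1:3] + 1
  expect_equal(count_displaced_atoms(before, after), 3)
  expect_equal(count_displaced_atoms(before, after,
                                     site_residues = c("A|1|", "A|2|")), 3)
  expect_equal(count_displaced_atoms(before, after,
                                     site_residues = "A|5|"), 0)
  expect_error(count_displaced_atoms(
    before, protein_structure(after$atoms[1:5, ])), "atom count")
})

test_that("curation filters commute on the planted fixture", {
  fx <- default_fixture()
  pol <- curation_policy()
  ligs <- extract_ligands(fx$structure, pol)
  expect_length(ligs, 1)
  # order 1: structure filters then site acceptance
  sf <- structure_filters(fx$structure, list(resolution = 2.0), pol)
  acc1 <- accept_site(sf$structure, ligs[[1]], pol)
  # order 2: site acceptance then structure filters
  acc2 <- accept_site(fx$structure, ligs[[1]], pol)
  sf2 <- structure_filters(fx$structure, list(resolution = 2.0), pol)
  expect_true(sf$accepted && sf2$accepted)
  expect_equal(acc1$accepted, acc2$accepted)
  expect_equal(acc1$site$n_site_atoms, acc2$site$n_site_atoms)
})
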