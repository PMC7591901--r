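test_that("atomic density follows the truncated Gaussian", {
  expect_identical(density_rho(0), 1.0)
  expect_equal(density_rho(4.0, 4.0), exp(-8))
  expect_identical(density_rho(4.0001, 4.0), 0.0)
  expect_equal(density_rho(c(0, 1, 5), 4), c(1, exp(-0.5), 0))
  expect_error(density_rho(-0.1), "non-negative")
})

test_that("stripping removes waters, hydrogens, and ions; typing fills channels", {
  atoms <- tibble::tibble(
    element = c("C", "H", "O", "O", "NA", "C"),
    name = c("CA", "HA", "O", "O", "NA", "CB"),
    x = 1:6 + 0, y = 0, z = 0,
    resname = c("ALA", "ALA", "ALA", "HOH", "NA", "LEU"),
    chain = "A", resno = c(1L, 1L, 1L, 2L, 3L, 4L),
    insert = "", hetero = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
    occupancy = 1, altloc = ""
  )
  st <- strip_and_type_atoms(protein_structure(atoms))
  expect_false(any(st$atoms$resname == "HOH"))
  expect_false(any(st$atoms$element == "H"))
  expect_false(any(st$atoms$resname == "NA"))   # monoatomic hetero ion
  # carbon of a hydrophobic residue is in the element-C, hydrophobic,
  # and occupancy channels
  cb <- st$atoms$channels[[which(st$atoms$name == "CB")]]
  expect_setequal(cb, c(1L, 5L, 11L))
  # every atom carries the occupancy channel
  expect_true(all(vapply(st$atoms$channels, function(ch) 11L %in% ch,
                         logical(1))))
})

test_that("stripping an all-solvent structure fails loudly", {
  atoms <- tibble::tibble(
    element = "O", name = "O", x = 0, y = 0, z = 0,
    resname = "HOH", chain = "A", resno = 1L, insert = "",
    hetero = FALSE, occupancy = 1, altloc = ""
  )
  expect_error(strip_and_type_atoms(protein_structure(atoms)), "empty")
})

test_that("altloc resolution keeps the highest-occupancy alternate", {
  atoms <- tibble::tibble(
    element = "C", name = "CA", x = c(0, 5), y = 0, z = 0,
    resname = "ALA", chain = "A", resno = 1L, insert = "",
    hetero = FALSE, occupancy = c(0.4, 0.6), altloc = c("A", "B")
  )
  st <- strip_and_type_atoms(protein_structure(atoms))
  expect_equal(nrow(st$atoms), 1L)
  expect_equal(st$atoms$x, 5)
})

test_that("tile origins follow the stride rule", {
  spec <- grid_spec(cube_size = 64, stride = 48, channel_scheme = "minimal")
  # per-axis tile count oracle: smallest k with cube + stride*(k-1) >= extent
  k_oracle <- function(extent, cube = 64, stride = 48) {
    k <- 1
    while (cube + stride * (k - 1) < extent) k <- k + 1
    k
  }
  cases <- list(
    list(ext = c(60, 60, 60), n = 1L),
    list(ext = c(100, 60, 60), n = k_oracle(100)),
    list(ext = c(160, 60, 60), n = k_oracle(160))
  )
  expect_equal(k_oracle(100), 2)
  expect_equal(k_oracle(160), 3)
  for (case in cases) {
    st <- make_structure(rbind(c(0, 0, 0), case$ext))
    st <- strip_and_type_atoms(st, "minimal")
    expect_equal(nrow(tile_origins(st, spec)), prod(vapply(
      case$ext, k_oracle, numeric(1))))
  }
})

test_that("every atom lies inside at least one tile", {
  fx <- default_fixture()
  st <- strip_and_type_atoms(fx$structure, "minimal")
  spec <- grid_spec(cube_size = 16, voxel_size = 2, stride = 12,
                    channel_scheme = "minimal")
  origins <- tile_origins(st, spec)
  cube_a <- spec$cube_size * spec$voxel_size
  p <- dplyr::filter(st$atoms, !hetero)
  covered <- vapply(seq_len(nrow(p)), function(a) {
    any(p$x[a] >= origins$ox & p$x[a] <= origins$ox + cube_a &
          p$y[a] >= origins$oy & p$y[a] <= origins$oy + cube_a &
          p$z[a] >= origins$oz & p$z[a] <= origins$oz + cube_a)
  }, logical(1))
  expect_true(all(covered))
})

test_that("voxelization matches the naive oracle and is additive", {
  spec <- grid_spec(cube_size = 8, voxel_size = 1, stride = 8,
                    channel_scheme = "minimal")
  set.seed(3)
  coords_a <- matrix(runif(9, 1, 7), 3)
  coords_b <- matrix(runif(6, 1, 7), 2)
  st_a <- strip_and_type_atoms(make_structure(coords_a), "minimal")
  st_b <- strip_and_type_atoms(make_structure(coords_b, element = "O",
                                              name = "O"), "minimal")
  st_ab <- strip_and_type_atoms(
    make_structure(rbind(coords_a, coords_b),
                   element = c(rep("C", 3), rep("O", 2)),
                   name = c(rep("CA", 3), rep("O", 2))), "minimal")
  origin <- c(0, 0, 0)
  ga <- voxelize(st_a, origin, spec)
  gb <- voxelize(st_b, origin, spec)
  gab <- voxelize(st_ab, origin, spec)
  expect_equal(ga$values, voxelize_oracle(st_a, origin, spec))
  expect_equal(gab$values, ga$values + gb$values)
})

test_that("a carbon at a voxel center contributes exactly 1 to its channels", {
  spec <- grid_spec(cube_size = 8, voxel_size = 1, stride = 8,
                    channel_scheme = "minimal")
  st <- strip_and_type_atoms(make_structure(rbind(c(3.5, 3.5, 3.5))),
                             "minimal")
  g <- voxelize(st, c(0, 0, 0), spec)
  expect_equal(g$values[4, 4, 4, 1], 1.0)  # carbon channel
  expect_equal(g$values[4, 4, 4, 4], 1.0)  # occupancy channel
  expect_equal(g$values[4, 4, 4, 2], 0.0)  # nitrogen channel untouched
  # two identical atoms double the density
  st2 <- strip_and_type_atoms(
    make_structure(rbind(c(3.5, 3.5, 3.5), c(3.5, 3.5, 3.5)),
                   resno = c(1L, 2L)), "minimal")
  g2 <- voxelize(st2, c(0, 0, 0), spec)
  expect_equal(g2$values[4, 4, 4, 1], 2.0)
})

test_that("voxel support is confined to the density cutoff", {
  spec <- grid_spec(cube_size = 16, voxel_size = 1, stride = 16,
                    channel_scheme = "minimal")
  set.seed(7)
  coords <- matrix(runif(12, 2, 14), 4)
  st <- strip_and_type_atoms(make_structure(coords), "minimal")
  g <- voxelize(st, c(0, 0, 0), spec)
  nz <- which(g$values[, , , 4] > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    ctr <- (nz[r, ] - 0.5) * spec$voxel_size
    dmin <- min(sqrt(colSums((t(coords) - ctr)^2)))
    expect_lte(dmin, spec$r_cutoff)
  }
})

test_that("translating atoms and origin together leaves the grid unchanged", {
  spec <- grid_spec(cube_size = 8, voxel_size = 1, stride = 8,
                    channel_scheme = "minimal")
  set.seed(11)
  coords <- matrix(runif(9, 1, 7), 3)
  shift <- c(13.7, -4.2, 8.9)
  st1 <- strip_and_type_atoms(make_structure(coords), "minimal")
  st2 <- strip_and_type_atoms(make_structure(sweep(coords, 2, -shift)),
                              "minimal")
  g1 <- voxelize(st1, c(0, 0, 0), spec)
  g2 <- voxelize(st2, shift, spec)
  expect_equal(g1$values, g2$values, tolerance = 1e-12)
})

test_that("empty-grid detection uses the mean-density threshold", {
  spec <- grid_spec(cube_size = 64, stride = 48)
  zero <- structure(list(values = array(0, c(64, 64, 64, 11)),
                         origin = c(0, 0, 0), spec = spec),
                    class = "voxel_grid")
  expect_true(is_empty_grid(zero))
  one <- zero
  one$values[1, 1, 1, 1] <- 1
  expect_equal(mean(one$values), 1 / (64^3 * 11))
  expect_true(is_empty_grid(one))          # 3.5e-7 < 1e-4
  # a real protein tile is far from empty
  fx <- default_fixture()
  st <- strip_and_type_atoms(fx$structure, "minimal")
  tspec <- grid_spec(16, 2, 12, channel_scheme = "minimal")
  g <- voxelize(st, as.numeric(tile_origins(st, tspec)[1, ]), tspec)
  expect_false(is_empty_grid(g))
})

test_that("unknown elements fall back to the occupancy channel with a warning", {
  st <- make_structure(rbind(c(0, 0, 0)), element = "SE", name = "SE",
                       resname = "MSE")
  expect_warning(typed <- strip_and_type_atoms(st), "occupancy")
  expect_identical(typed$atoms$channels[[1]], 11L)
})
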