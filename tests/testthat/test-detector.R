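toy_cfg <- toy_model_config(seed = 5)
toy_spec <- spec_for_config(toy_cfg)

test_that("target encoding inverts decoding", {
  spec <- grid_spec(cube_size = 64, stride = 48, channel_scheme = "minimal")
  # center at origin + (4,4,4) with 8-voxel cells of 1 A: cell (0,0,0),
  # fractional position (0.5, 0.5, 0.5)
  sites <- tibble::tibble(cx = 4, cy = 4, cz = 4)
  tgt <- encode_targets(sites, c(0, 0, 0), spec)
  expect_equal(sum(tgt[, , , 1]), 1)
  expect_equal(tgt[1, 1, 1, ], c(1, 0.5, 0.5, 0.5))
  # no sites -> all-zero score plane
  expect_equal(sum(encode_targets(sites[0, ], c(0, 0, 0), spec)), 0)
})

test_that("decoding follows the cell-to-Cartesian rule", {
  spec <- grid_spec(cube_size = 64, stride = 48, channel_scheme = "minimal")
  tensor <- array(0, c(8, 8, 8, 4))
  tensor[1, 1, 1, ] <- c(0.9, 0.5, 0.5, 0.5)
  dec <- decode_detections(tensor, c(0, 0, 0), spec)
  hit <- dec[dec$i == 0 & dec$j == 0 & dec$k == 0, ]
  expect_equal(c(hit$x, hit$y, hit$z), c(4, 4, 4))
  # far-corner cell with fractions near 1 approaches the tile's far corner
  tensor[8, 8, 8, ] <- c(0.9, 1 - 1e-9, 1 - 1e-9, 1 - 1e-9)
  dec <- decode_detections(tensor, c(10, 10, 10), spec)
  far <- dec[dec$i == 7 & dec$j == 7 & dec$k == 7, ]
  expect_equal(c(far$x, far$y, far$z), c(74, 74, 74), tolerance = 1e-7)
})

test_that("encode-decode round trip recovers random centers", {
  spec <- grid_spec(cube_size = 64, stride = 48, channel_scheme = "minimal")
  set.seed(99)
  n <- 1000
  centers <- matrix(runif(3 * n, 0.01, 63.99), n, 3)
  worst <- 0
  for (i in seq_len(n)) {
    sites <- tibble::tibble(cx = centers[i, 1], cy = centers[i, 2],
                            cz = centers[i, 3])
    tgt <- encode_targets(sites, c(0, 0, 0), spec)
    dec <- decode_detections(tgt, c(0, 0, 0), spec)
    hit <- dec[dec$score == 1, ]
    err <- sqrt((hit$x - centers[i, 1])^2 + (hit$y - centers[i, 2])^2 +
                  (hit$z - centers[i, 3])^2)
    worst <- max(worst, err)
  }
  expect_lt(worst, 1e-6)
})

test_that("a center on a cell boundary belongs to the lower-index cell", {
  spec <- grid_spec(cube_size = 64, stride = 48, channel_scheme = "minimal")
  tgt <- encode_targets(tibble::tibble(cx = 8, cy = 8, cz = 8),
                        c(0, 0, 0), spec)
  expect_equal(tgt[2, 2, 2, 1], 1)
  expect_equal(tgt[2, 2, 2, 2:4], c(0, 0, 0))
})

test_that("two centers in one cell keep the larger ligand", {
  spec <- grid_spec(cube_size = 64, stride = 48, channel_scheme = "minimal")
  sites <- tibble::tibble(cx = c(2, 3), cy = 2, cz = 2,
                          n_ligand_atoms = c(15L, 30L),
                          ligand_resno = c(1L, 2L))
  tgt <- encode_targets(sites, c(0, 0, 0), spec)
  expect_equal(sum(tgt[, , , 1]), 1)
  expect_equal(tgt[1, 1, 1, 2], 3 / 8)     # the 30-atom ligand's center
})

test_that("detection loss reproduces hand-computed values", {
  perfect <- array(0, c(8, 8, 8, 4))
  perfect[3, 4, 5, ] <- c(1, 0.2, 0.4, 0.6)
  expect_equal(detection_loss(perfect, perfect, gamma = 0), 0)

  one_fp <- array(0, c(8, 8, 8, 4))
  one_fp[1, 1, 1, 1] <- 1
  expect_equal(detection_loss(one_fp, array(0, c(8, 8, 8, 4)), gamma = 0),
               1.0)

  # one positive cell, coordinate error 0.1 per axis, lambda 5:
  # 5 * 3 * 0.01 = 0.15
  target <- array(0, c(8, 8, 8, 4))
  target[2, 2, 2, ] <- c(1, 0.5, 0.5, 0.5)
  pred <- target
  pred[2, 2, 2, 2:4] <- 0.6
  expect_equal(detection_loss(pred, target, lambda = 5, gamma = 0), 0.15,
               tolerance = 1e-9)
  # the L2 term adds gamma * sum(W^2)
  expect_equal(detection_loss(perfect, perfect, gamma = 1e-3,
                              weights = list(matrix(2, 2, 2))),
               1e-3 * 16)
})

test_that("loss ignores coordinates exactly where the target score is zero", {
  set.seed(21)
  target <- array(0, c(8, 8, 8, 4))
  pred1 <- array(runif(8^3 * 4), c(8, 8, 8, 4))
  pred2 <- pred1
  pred2[, , , 2:4] <- runif(8^3 * 3)       # different coordinates
  pred2[, , , 1] <- pred1[, , , 1]
  expect_equal(detection_loss(pred1, target, gamma = 0),
               detection_loss(pred2, target, gamma = 0))
  # and with lambda = 0 coordinates never matter
  target[5, 5, 5, ] <- c(1, 0.5, 0.5, 0.5)
  expect_equal(detection_loss(pred1, target, lambda = 0, gamma = 0),
               detection_loss(pred2, target, lambda = 0, gamma = 0))
})

test_that("the default architecture has the published shape", {
  m <- build_model(model_config())
  expect_equal(n_conv_layers(m), 10L)
  expect_equal(model_output_shape(m), c(8, 8, 8, 4))
  expect_equal(m$config$cube_size, 64L)
  expect_equal(m$config$n_channels, 11L)
  # a pooling plan that cannot reach 8 cells is rejected
  expect_error(model_config(cube_size = 32, pool_after = c(2, 5, 8)),
               "8 cells")
  expect_error(model_config(conv_filters = c(8, 8)), "4 filters")
})

test_that("the forward pass emits sigmoid-bounded outputs of the right shape", {
  m <- build_model(toy_cfg)
  set.seed(1)
  x <- array(rnorm(16^3 * 4, sd = 3), c(16, 16, 16, 4))
  fwd <- model_forward(m, list(x))
  expect_equal(dim(fwd$Y), c(512, 4))
  expect_true(all(fwd$Y > 0 & fwd$Y < 1))
})

test_that("backpropagation matches finite differences on a tiny network", {
  cfg <- model_config(conv_filters = c(3, 4), pool_after = integer(0),
                      cube_size = 8, channel_scheme = "minimal",
                      voxel_size = 2, seed = 3)
  m <- build_model(cfg)
  set.seed(4)
  x <- array(rnorm(8^3 * 4), c(8, 8, 8, 4))
  target <- matrix(0, 512, 4)
  target[c(5, 100), ] <- cbind(1, 0.3, 0.6, 0.9)
  loss_of <- function(model) {
    fwd <- model_forward(model, list(x), training = TRUE)
    s <- target[, 1]
    sum((s - fwd$Y[, 1])^2) +
      5 * sum(s * rowSums((target[, 2:4] - fwd$Y[, 2:4])^2))
  }
  fwd <- model_forward(m, list(x), training = TRUE)
  s <- target[, 1]
  dY <- cbind(2 * (fwd$Y[, 1] - s), 2 * 5 * s * (fwd$Y[, 2:4] - target[, 2:4]))
  grads <- model_backward(fwd, dY)
  eps <- 1e-5
  for (l in 1:2) {
    for (pick in list(c(1, 1), c(14, 2))) {
      m_hi <- m; m_lo <- m
      m_hi$layers[[l]]$W[pick[1], pick[2]] <- m$layers[[l]]$W[pick[1], pick[2]] + eps
      m_lo$layers[[l]]$W[pick[1], pick[2]] <- m$layers[[l]]$W[pick[1], pick[2]] - eps
      num <- (loss_of(m_hi) - loss_of(m_lo)) / (2 * eps)
      expect_equal(grads[[l]]$dW[pick[1], pick[2]], num, tolerance = 1e-4)
    }
  }
  # gradient reaches every trainable tensor
  expect_true(all(vapply(seq_along(grads), function(l)
    any(grads[[l]]$dW != 0) && any(grads[[l]]$db != 0), logical(1))))
  expect_true(any(grads[[1]]$dgamma != 0) && any(grads[[1]]$dbeta != 0))
})

test_that("short training on one planted-site tile reduces the loss", {
  fx <- default_fixture()
  st <- strip_and_type_atoms(fx$structure, "minimal")
  origin <- as.numeric(tile_origins(st, toy_spec)[1, ])
  g <- voxelize(st, origin, toy_spec)
  tgt <- encode_targets(fx$sites, origin, toy_spec)
  cfg <- toy_model_config(epochs = 10, seed = 5)
  m <- train_detector(list(g), list(tgt), config = cfg)
  expect_lt(dplyr::last(m$history$loss), m$history$loss[1])
  expect_equal(nrow(m$history), 10)
  # reproducibility: same config and data give the identical history
  m2 <- train_detector(list(g), list(tgt), config = cfg)
  expect_equal(m$history$loss, m2$history$loss)
  expect_error(train_detector(list(), list(), config = cfg), "empty")
})

test_that("rotational augmentation re-images structures every epoch", {
  fx <- default_fixture()
  st <- strip_and_type_atoms(fx$structure, "minimal")
  cfg <- toy_model_config(epochs = 4, seed = 5)
  m <- train_detector(config = cfg,
                      augment = list(structures = list(st),
                                     sites = list(fx$sites),
                                     spec = toy_spec))
  expect_equal(nrow(m$history), 4)
  expect_true(all(is.finite(m$history$loss)))
})

test_that("tidy and glance summarize a trained detector", {
  fx <- default_fixture()
  st <- strip_and_type_atoms(fx$structure, "minimal")
  origin <- as.numeric(tile_origins(st, toy_spec)[1, ])
  g <- voxelize(st, origin, toy_spec)
  tgt <- encode_targets(fx$sites, origin, toy_spec)
  m <- train_detector(list(g), list(tgt),
                      config = toy_model_config(epochs = 3, seed = 5))
  expect_equal(nrow(tidy(m)), 3)
  gl <- glance(m)
  expect_equal(gl$n_layers, 4L)
  expect_equal(gl$epochs_trained, 3L)
  # checkpoints round-trip
  path <- withr::local_tempfile(fileext = ".rds")
  save_detector(m, path)
  m2 <- load_detector(path)
  expect_equal(m2$layers, m$layers)
})

test_that("cube-rotation augmentation moves targets rigidly with the grid", {
  spec <- grid_spec(cube_size = 16, voxel_size = 2, stride = 12,
                    channel_scheme = "minimal")
  ops <- voxsite:::.OCTAHEDRAL_OPS
  expect_length(ops, 24)
  set.seed(77)
  for (t in 1:50) {
    ctr <- runif(3, 0.5, 31.5)
    tgt <- encode_targets(tibble::tibble(cx = ctr[1], cy = ctr[2],
                                         cz = ctr[3]), c(0, 0, 0), spec)
    op <- ops[[sample(24, 1)]]
    dec <- decode_detections(voxsite:::.rotate_target(tgt, op),
                             c(0, 0, 0), spec)
    hit <- dec[dec$score == 1, ]
    expect_equal(nrow(hit), 1)
    expected <- vapply(1:3, function(a) {
      if (op$flip[op$perm[a]]) 32 - ctr[op$perm[a]] else ctr[op$perm[a]]
    }, numeric(1))
    expect_equal(c(hit$x, hit$y, hit$z), expected, tolerance = 1e-9)
  }
  # training with grid-space augmentation runs and optimizes
  fx <- default_fixture()
  st <- strip_and_type_atoms(fx$structure, "minimal")
  origin <- as.numeric(tile_origins(st, toy_spec)[1, ])
  g <- voxelize(st, origin, toy_spec)
  tgt <- encode_targets(fx$sites, origin, toy_spec)
  m <- train_detector(list(g), list(tgt),
                      config = toy_model_config(epochs = 6, seed = 5),
                      augment = "octahedral")
  expect_equal(nrow(m$history), 6)
  expect_true(all(is.finite(m$history$loss)))
})
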