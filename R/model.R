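#' Detection model configuration
#'
#' Architecture and training hyper-parameters of the cell-based 3D
#' detection network. The default profile is the full published-scale
#' architecture: ten convolutional layers (32, 32, 32, 32, 32, 64, 64, 64,
#' 128, 4 filters), 3x3x3 kernels, stride-2 max pooling after layers 2, 5
#' and 8 (64 voxels -> 8 cells per axis), batch-norm + ReLU on every layer
#' but the last, and sigmoid on all four outputs. The composite loss is
#' squared score error plus `lambda` times the squared in-cell coordinate
#' error on positive cells plus `gamma` times the L2 norm of the
#' convolution weights.
#'
#' @param conv_filters Filter counts per layer; last must be 4.
#' @param pool_after Layer indices followed by stride-2 max pooling.
#' @param kernel Kernel edge (only 3 supported).
#' @param cube_size Input tile edge in voxels; `cube_size / 2^length(pool_after)`
#'   must equal 8 (the output cell resolution).
#' @param channel_scheme Density channel scheme name (fixes input channels).
#' @param voxel_size Angstroms per voxel.
#' @param lambda Coordinate-loss weight (default 5; the published tuning
#'   table favors 10 -- both are supported, 5 being the loss equation's
#'   stated coefficient).
#' @param gamma L2 regularization weight (default 1e-5); applies to
#'   convolution weights only, not batch-norm parameters.
#' @param lr_start,lr_end Learning-rate schedule endpoints (exponential
#'   decay across the epoch budget; defaults 1e-3 -> 1e-5).
#' @param epochs Training epochs (default 400).
#' @param minibatch Minibatch size in tiles (default 16).
#' @param seed Integer seed controlling initialization and batching.
#' @return A `model_config` object. `cell_size` (voxels per output cell)
#'   is derived as `cube_size / 8`.
#' @export
model_config <- function(conv_filters = c(32, 32, 32, 32, 32, 64, 64, 64, 128, 4),
                         pool_after = c(2, 5, 8), kernel = 3L,
                         cube_size = 64L, channel_scheme = "default",
                         voxel_size = 1.0,
                         lambda = 5, gamma = 1e-5,
                         lr_start = 1e-3, lr_end = 1e-5,
                         epochs = 400L, minibatch = 16L, seed = 1L) {
  cube_size <- as.integer(cube_size)
  if (kernel != 3L) rlang::abort("only 3x3x3 kernels are supported")
  if (utils::tail(conv_filters, 1) != 4) {
    rlang::abort("last layer must have 4 filters (score + 3 coordinates)")
  }
  if (length(pool_after) > 0 &&
      (any(pool_after < 1) || any(pool_after >= length(conv_filters)))) {
    rlang::abort("pool_after indices must name non-final layers")
  }
  out_cells <- cube_size / 2^length(pool_after)
  if (out_cells != 8) {
    rlang::abort(sprintf(
      "poolings must reduce the cube to 8 cells per axis (got %g)", out_cells))
  }
  structure(
    list(conv_filters = as.integer(conv_filters),
         pool_after = as.integer(pool_after), kernel = 3L,
         cube_size = cube_size, channel_scheme = channel_scheme,
         n_channels = channel_scheme_size(channel_scheme),
         voxel_size = voxel_size,
         cell_size = cube_size %/% 8L,
         lambda = lambda, gamma = gamma,
         lr_start = lr_start, lr_end = lr_end,
         epochs = as.integer(epochs), minibatch = as.integer(minibatch),
         seed = as.integer(seed)),
    class = "model_config"
  )
}

#' Desk-scale detector profile
#'
#' A light configuration for CPU-scale experiments: 16-voxel tiles of
#' 2-angstrom voxels (32 angstrom coverage), the 4-channel minimal scheme,
#' four convolutional layers (8, 16, 16, 4) with one pooling (16 -> 8
#' cells of 4 angstroms). Coarser voxels trade accuracy for speed, which
#' is the right trade at desk scale.
#'
#' @param ... Overrides passed to [model_config()].
#' @return A `model_config`.
#' @export
toy_model_config <- function(...) {
  defaults <- list(conv_filters = c(8, 16, 16, 4), pool_after = 1L,
                   cube_size = 16L, channel_scheme = "minimal",
                   voxel_size = 2.0, epochs = 30L, lr_end = 1e-4)
  args <- utils::modifyList(defaults, list(...))
  do.call(model_config, args)
}

#' Grid specification matching a model configuration
#'
#' @param config A `model_config`.
#' @param stride Tiling stride in voxels (default `3 * cube_size / 4`).
#' @return A [grid_spec()].
#' @export
spec_for_config <- function(config, stride = NULL) {
  if (is.null(stride)) stride <- as.integer(config$cube_size * 3L / 4L)
  grid_spec(cube_size = config$cube_size, voxel_size = config$voxel_size,
            stride = stride, channel_scheme = config$channel_scheme)
}

#' Build the detection network
#'
#' Instantiates the layers described by a [model_config()]: each
#' convolutional layer carries He-initialized 3x3x3 weights, and all
#' layers except the last are followed by batch normalization and ReLU
#' (plus stride-2 max pooling where configured). The last layer feeds a
#' sigmoid so all four outputs (score and in-cell coordinates) lie in
#' (0, 1).
#'
#' @param config A `model_config`.
#' @return A `site_detector` object (layers + config).
#' @export
build_model <- function(config = model_config()) {
  withr::with_seed(config$seed, {
    n_layers <- length(config$conv_filters)
    cin <- config$n_channels
    layers <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      f <- config$conv_filters[l]
      fan_in <- 27L * cin
      W <- matrix(stats::rnorm(fan_in * f, sd = sqrt(2 / fan_in)), fan_in, f)
      b <- numeric(f)
      last <- l == n_layers
      layers[[l]] <- list(
        W = W, b = b,
        bn = if (!last) list(gamma = rep(1, f), beta = numeric(f),
                             running = list(mean = numeric(f),
                                            var = rep(1, f))),
        pool = l %in% config$pool_after,
        last = last
      )
      cin <- f
    }
    structure(list(layers = layers, config = config,
                   spec = spec_for_config(config)),
              class = "site_detector")
  })
}

#' @export
print.site_detector <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<site_detector> %d conv layers (%s), input %d^3 x %d, output 8^3 x 4%s\n",
    length(cfg$conv_filters),
    paste(cfg$conv_filters, collapse = ","),
    cfg$cube_size, cfg$n_channels,
    if (!is.null(x$history)) sprintf(", trained %d epochs", max(x$history$epoch))
    else " (untrained)"))
  invisible(x)
}

#' Number of core convolutional layers
#' @param model A `site_detector`.
#' @return Integer layer count.
#' @export
n_conv_layers <- function(model) length(model$layers)

#' Output shape of the detector
#' @param model A `site_detector`.
#' @return Integer vector (cells per axis x 3, components).
#' @export
model_output_shape <- function(model) {
  n <- model$config$cube_size / 2^length(model$config$pool_after)
  c(n, n, n, utils::tail(model$config$conv_filters, 1))
}

# Forward pass. X: list of input arrays (n, n, n, C) (a batch).
# Returns list(Y = (B*512) x 4 sigmoid outputs, caches for backward).
model_forward <- function(model, X, training = FALSE) {
  cfg <- model$config
  B <- length(X)
  n <- cfg$cube_size
  n3 <- n^3
  A <- matrix(0, B * n3, cfg$n_channels)
  for (b in seq_len(B)) {
    s <- X[[b]]
    dim(s) <- c(n3, cfg$n_channels)
    A[((b - 1L) * n3 + 1L):(b * n3), ] <- s
  }
  caches <- vector("list", length(model$layers))
  for (l in seq_along(model$layers)) {
    ly <- model$layers[[l]]
    cv <- conv3d_forward(A, n, B, ly$W, ly$b)
    cache <- list(n_in = n, P = cv$P)
    A <- cv$Y
    if (!ly$last) {
      bn <- bn_forward(A, ly$bn$gamma, ly$bn$beta, ly$bn$running, training)
      if (training) model$layers[[l]]$bn$running <- bn$running
      cache$bn <- list(xhat = bn$xhat, inv_std = bn$inv_std)
      A <- bn$Y
      cache$relu_mask <- A > 0
      A <- A * cache$relu_mask
      if (ly$pool) {
        mp <- maxpool_forward(A, n, B)
        cache$pool <- list(argmax = mp$argmax, m = mp$m)
        A <- mp$Y
        n <- mp$m
      }
    } else {
      A <- sigmoid(A)
      cache$out <- A
    }
    caches[[l]] <- cache
  }
  list(Y = A, caches = caches, model = model, B = B)
}

# Backward pass from dY (gradient at the sigmoid output).
# Returns per-layer gradients (dW, db, dgamma, dbeta).
model_backward <- function(fwd, dY) {
  model <- fwd$model
  B <- fwd$B
  grads <- vector("list", length(model$layers))
  out <- fwd$caches[[length(model$layers)]]$out
  dA <- dY * out * (1 - out)     # through the sigmoid
  for (l in rev(seq_along(model$layers))) {
    ly <- model$layers[[l]]
    cache <- fwd$caches[[l]]
    n <- cache$n_in
    if (!ly$last) {
      if (ly$pool) dA <- maxpool_backward(dA, cache$pool, n, B)
      dA <- dA * cache$relu_mask
      bn <- bn_backward(dA, cache$bn, ly$bn$gamma)
      dA <- bn$dX
      grads[[l]] <- list(dgamma = bn$dgamma, dbeta = bn$dbeta)
    } else {
      grads[[l]] <- list()
    }
    cv <- conv3d_backward(dA, cache, ly$W, n, B)
    grads[[l]]$dW <- cv$dW
    grads[[l]]$db <- cv$db
    dA <- cv$dX
  }
  grads
}

#' Composite detection loss
#'
#' `sum((s - s_hat)^2) + lambda * sum(s * ((x - x_hat)^2 + (y - y_hat)^2 +
#' (z - z_hat)^2)) + gamma * L2`, summed over the 512 cells of one tile.
#' The coordinate term only contributes where the true score `s` is 1; the
#' L2 term is the squared norm of the convolution weights.
#'
#' @param pred Predicted tensor, array `8 x 8 x 8 x 4` (score then x, y, z).
#' @param target Target tensor of the same shape (binary score channel).
#' @param lambda Coordinate-term weight.
#' @param gamma L2 weight.
#' @param weights Optional list of weight matrices entering the L2 term.
#' @return Scalar loss.
#' @export
detection_loss <- function(pred, target, lambda = 5, gamma = 1e-5,
                           weights = NULL) {
  P <- matrix(pred, ncol = 4)
  T_ <- matrix(target, ncol = 4)
  s <- T_[, 1]
  score_term <- sum((s - P[, 1])^2)
  coord_term <- lambda * sum(s * rowSums((T_[, 2:4, drop = FALSE] -
                                            P[, 2:4, drop = FALSE])^2))
  l2 <- if (is.null(weights)) 0 else sum(vapply(weights, function(w)
    sum(w^2), numeric(1)))
  score_term + coord_term + gamma * l2
}

.loss_and_grad <- function(Y, T_, lambda, B) {
  s <- T_[, 1]
  ds <- Y[, 1] - s
  dcoord <- (Y[, 2:4, drop = FALSE] - T_[, 2:4, drop = FALSE]) * s
  score_term <- sum(ds^2) / B
  coord_term <- lambda * sum(s * rowSums((Y[, 2:4, drop = FALSE] -
                                            T_[, 2:4, drop = FALSE])^2)) / B
  dY <- cbind(2 * ds, 2 * lambda * dcoord) / B
  list(score = score_term, coord = coord_term, dY = dY)
}

.adam_init <- function(model) {
  lapply(model$layers, function(ly) {
    g <- list(W = list(m = ly$W * 0, v = ly$W * 0),
              b = list(m = ly$b * 0, v = ly$b * 0))
    if (!is.null(ly$bn)) {
      g$gamma <- list(m = ly$bn$gamma * 0, v = ly$bn$gamma * 0)
      g$beta <- list(m = ly$bn$beta * 0, v = ly$bn$beta * 0)
    }
    g
  })
}

.adam_update <- function(val, grad, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(val = val - lr * mhat / (sqrt(vhat) + eps), st = st)
}

#' Train the detection network
#'
#' Optimizes the composite loss with Adam over minibatches of tiles, with
#' the learning rate decaying exponentially from `lr_start` to `lr_end`
#' across the epoch budget. With `augment`, every structure is re-imaged
#' each epoch under a fresh random rigid rotation (implicit rotational
#' data augmentation); this requires the original structures and sites
#' rather than fixed grids.
#'
#' @param grids List of input tiles: `voxel_grid` objects or plain arrays
#'   (`cube^3 x channels`).
#' @param targets List of target tensors (`8 x 8 x 8 x 4` arrays), parallel
#'   to `grids`. Ignored when `augment` data is given.
#' @param config A `model_config`.
#' @param model Optional pre-built / warm-start `site_detector`.
#' @param augment Rotational augmentation: `NULL` (none), the string
#'   `"octahedral"` (each epoch every stored tile and its target are
#'   rotated by a random proper rotation of the cube -- exact on the
#'   grid, no re-voxelization), or a list with `structures`
#'   (channel-typed), `sites` (list of site tibbles), and optionally
#'   `spec` (a [grid_spec()]) for full random-orientation re-imaging.
#' @param verbose Print per-epoch losses.
#' @return The trained `site_detector`, with a `history` tibble
#'   (`epoch`, `loss`, `score_term`, `coord_term`, `l2_term`) attached.
#' @export
train_detector <- function(grids = NULL, targets = NULL,
                           config = model_config(), model = NULL,
                           augment = NULL, verbose = FALSE) {
  if (is.null(model)) model <- build_model(config) else config <- model$config
  aug_mode <- if (is.null(augment)) "none"
              else if (identical(augment, "octahedral")) "octahedral"
              else "reimage"
  if (aug_mode != "reimage") {
    if (length(grids) == 0) rlang::abort("empty training dataset")
    G0 <- lapply(grids, function(g) if (inherits(g, "voxel_grid")) g$values else g)
    A0 <- lapply(targets, function(t) array(t, dim = c(8, 8, 8, 4)))
    X0 <- G0
    T0 <- lapply(A0, function(t) matrix(t, ncol = 4))
    n_samples <- length(X0)
  } else {
    spec <- augment$spec %||% spec_for_config(config)
    n_samples <- length(augment$structures)
    if (n_samples == 0) rlang::abort("empty training dataset")
  }
  adam <- .adam_init(model)
  hist <- vector("list", config$epochs)
  step <- 0L
  withr::with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      lr <- config$lr_start *
        (config$lr_end / config$lr_start)^(if (config$epochs > 1)
          (epoch - 1) / (config$epochs - 1) else 0)
      if (aug_mode == "reimage") {
        rotated <- .augment_epoch(augment$structures, augment$sites, spec)
        X0 <- rotated$grids
        T0 <- rotated$targets
      } else if (aug_mode == "octahedral") {
        ops <- sample.int(length(.OCTAHEDRAL_OPS), n_samples, replace = TRUE)
        X0 <- lapply(seq_len(n_samples), function(i)
          .rotate_array(G0[[i]], .OCTAHEDRAL_OPS[[ops[i]]]))
        T0 <- lapply(seq_len(n_samples), function(i)
          matrix(.rotate_target(A0[[i]], .OCTAHEDRAL_OPS[[ops[i]]]), ncol = 4))
      }
      idx <- sample.int(n_samples)
      ep_score <- ep_coord <- 0
      batches <- split(idx, ceiling(seq_along(idx) / config$minibatch))
      for (batch in batches) {
        B <- length(batch)
        fwd <- model_forward(model, X0[batch], training = TRUE)
        model <- fwd$model  # running BN stats updated
        T_ <- do.call(rbind, T0[batch])
        lg <- .loss_and_grad(fwd$Y, T_, config$lambda, B)
        ep_score <- ep_score + lg$score * B
        ep_coord <- ep_coord + lg$coord * B
        grads <- model_backward(fwd, lg$dY)
        step <- step + 1L
        for (l in seq_along(model$layers)) {
          gW <- grads[[l]]$dW + 2 * config$gamma * model$layers[[l]]$W
          up <- .adam_update(model$layers[[l]]$W, gW, adam[[l]]$W, lr, step)
          model$layers[[l]]$W <- up$val; adam[[l]]$W <- up$st
          up <- .adam_update(model$layers[[l]]$b, grads[[l]]$db,
                             adam[[l]]$b, lr, step)
          model$layers[[l]]$b <- up$val; adam[[l]]$b <- up$st
          if (!is.null(model$layers[[l]]$bn)) {
            up <- .adam_update(model$layers[[l]]$bn$gamma, grads[[l]]$dgamma,
                               adam[[l]]$gamma, lr, step)
            model$layers[[l]]$bn$gamma <- up$val; adam[[l]]$gamma <- up$st
            up <- .adam_update(model$layers[[l]]$bn$beta, grads[[l]]$dbeta,
                               adam[[l]]$beta, lr, step)
            model$layers[[l]]$bn$beta <- up$val; adam[[l]]$beta <- up$st
          }
        }
      }
      l2 <- config$gamma * sum(vapply(model$layers, function(ly)
        sum(ly$W^2), numeric(1)))
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch, loss = ep_score / n_samples + ep_coord / n_samples + l2,
        score_term = ep_score / n_samples, coord_term = ep_coord / n_samples,
        l2_term = l2)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f (score %.4f coord %.4f l2 %.4f)",
                        epoch, hist[[epoch]]$loss, hist[[epoch]]$score_term,
                        hist[[epoch]]$coord_term, l2))
      }
    }
  })
  model$history <- dplyr::bind_rows(hist)
  model
}

.augment_epoch <- function(structures, sites, spec) {
  grids <- vector("list", length(structures))
  targets <- vector("list", length(structures))
  for (i in seq_along(structures)) {
    rot <- .random_rotation()
    ctr <- structure_centroid(structures[[i]])
    st <- rotate_structure(structures[[i]], rot, ctr)
    s <- sites[[i]]
    xyz <- sweep(sweep(as.matrix(s[, c("cx", "cy", "cz")]), 2, ctr) %*%
                   t(rot), 2, ctr, FUN = "+")
    s$cx <- xyz[, 1]; s$cy <- xyz[, 2]; s$cz <- xyz[, 3]
    origin <- as.numeric(tile_origins(st, spec)[1, ])
    grids[[i]] <- voxelize(st, origin, spec)$values
    targets[[i]] <- matrix(encode_targets(s, origin, spec), ncol = 4)
  }
  list(grids = grids, targets = targets)
}

#' Save / load a trained detector
#'
#' Checkpoints use R's standard serialization with the configuration
#' embedded in the object.
#'
#' @param model A `site_detector`.
#' @param path File path.
#' @return `save_detector` returns `path` invisibly; `load_detector`
#'   returns the model.
#' @export
save_detector <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) readRDS(path)
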