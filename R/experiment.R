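#' Desk-scale parameter-recovery experiment
#'
#' The package's end-to-end study condition: generate planted-pocket
#' training structures, train the desk-scale detector profile
#' ([toy_model_config()]: 16-voxel tiles of 2 angstrom voxels, minimal
#' channels, 30 epochs of Adam on minibatches of 8 with the learning
#' rate decaying 1e-3 to 5e-4, random cube-rotation augmentation each
#' epoch), then predict on held-out structures and score them under the
#' 4-angstrom center criterion at the benchmarking score threshold
#' (0.01). All randomness derives from `base_seed`.
#'
#' @param base_seed Integer seed controlling fixture generation,
#'   initialization, and batching.
#' @param n_train Training structures (default 400).
#' @param n_test Held-out structures (default 50).
#' @param epochs Training epochs (default 30).
#' @param verbose Print per-epoch losses.
#' @return A list: `model` (the trained `site_detector`), `evaluation`
#'   (a `site_eval` on the held-out set), `tp_center_errors` (distances
#'   from each true-positive prediction to its matched site center,
#'   angstroms), `predictions`, `sites`.
#' @export
run_detection_experiment <- function(base_seed = 0L, n_train = 400L,
                                     n_test = 50L, epochs = 30L,
                                     verbose = FALSE) {
  cfg <- toy_model_config(epochs = epochs, minibatch = 8L,
                          lr_start = 1e-3, lr_end = 5e-4,
                          seed = base_seed + 17L)
  spec <- spec_for_config(cfg)
  prep <- function(seeds) {
    lapply(seeds, function(s) {
      fx <- generate_structure(fixture_spec(seed = s))
      st <- strip_and_type_atoms(fx$structure, cfg$channel_scheme)
      origin <- as.numeric(tile_origins(st, spec)[1, ])
      list(grid = voxelize(st, origin, spec)$values,
           target = encode_targets(fx$sites, origin, spec),
           fx = fx)
    })
  }
  train <- prep(base_seed + seq_len(n_train))
  test <- prep(base_seed + 100000L + seq_len(n_test))
  model <- train_detector(lapply(train, `[[`, "grid"),
                          lapply(train, `[[`, "target"),
                          config = cfg, augment = "octahedral",
                          verbose = verbose)
  preds <- purrr::map_dfr(seq_along(test), function(i) {
    p <- predict_sites(test[[i]]$fx$structure, model,
                       nms_params(s_threshold = 0.01, d_threshold = 8))
    if (nrow(p) > 0) p$structure_id <- i
    p
  })
  sites <- purrr::map_dfr(seq_along(test), function(i) {
    dplyr::mutate(test[[i]]$fx$sites, structure_id = i)
  })
  ev <- evaluate_predictions(preds, sites, match_criterion("center", 4))
  tp <- ev$labels[ev$labels$tp, , drop = FALSE]
  tp_err <- vapply(seq_len(nrow(tp)), function(i) {
    s <- sites[sites$structure_id == tp$structure_id[i], , drop = FALSE]
    min(sqrt((tp$x[i] - s$cx)^2 + (tp$y[i] - s$cy)^2 + (tp$z[i] - s$cz)^2))
  }, numeric(1))
  list(model = model, evaluation = ev, tp_center_errors = tp_err,
       predictions = preds, sites = sites)
}
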