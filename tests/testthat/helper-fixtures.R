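# Shared fixtures and independent oracles for the test suite.

# bare-bones structure builder: one atom per row of `coords`
make_structure <- function(coords, element = "C", resno = NULL,
                           hetero = FALSE, resname = "ALA", chain = "A",
                           name = "CA") {
  n <- nrow(coords)
  protein_structure(tibble::tibble(
    element = rep_len(element, n), name = rep_len(name, n),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    resname = rep_len(resname, n), chain = rep_len(chain, n),
    resno = as.integer(resno %||% seq_len(n)),
    insert = "", hetero = rep_len(hetero, n),
    occupancy = 1, altloc = ""
  ))
}

`%||%` <- rlang::`%||%`

# cached default planted-pocket fixture (built once per test run)
default_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_structure(fixture_spec(seed = 42))
    cache
  }
})

# naive voxelization oracle: triple loop over voxels x atoms
voxelize_oracle <- function(structure, origin, spec) {
  n <- spec$cube_size
  v <- spec$voxel_size
  p <- dplyr::filter(structure$atoms, !hetero)
  vals <- array(0, dim = c(n, n, n, spec$n_channels))
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    ctr <- origin + (c(i, j, k) - 0.5) * v
    for (a in seq_len(nrow(p))) {
      r <- sqrt(sum((ctr - c(p$x[a], p$y[a], p$z[a]))^2))
      if (r <= spec$r_cutoff) {
        for (ch in p$channels[[a]]) {
          vals[i, j, k, ch] <- vals[i, j, k, ch] + exp(-r^2 / 2)
        }
      }
    }
  }
  vals
}

# independent greedy-NMS oracle: plain quadratic implementation
nms_oracle <- function(preds, params) {
  preds <- preds[preds$score >= params$s_threshold, , drop = FALSE]
  preds <- preds[order(-preds$score, preds$x, preds$y, preds$z), ,
                 drop = FALSE]
  kept <- preds[0, ]
  while (nrow(preds) > 0) {
    seed <- preds[1, ]
    kept <- rbind(kept, seed)
    d <- sqrt((preds$x - seed$x)^2 + (preds$y - seed$y)^2 +
                (preds$z - seed$z)^2)
    preds <- preds[d > params$d_threshold, , drop = FALSE]
  }
  utils::head(kept, if (is.finite(params$n_top)) params$n_top else nrow(kept))
}

# threshold-sweep AP oracle: integrate precision over recall across every
# distinct score threshold
ap_oracle <- function(scores, tp, n_sites) {
  ord <- order(-scores)
  scores <- scores[ord]; tp <- tp[ord]
  thresholds <- sort(unique(scores), decreasing = TRUE)
  r_prev <- 0
  ap <- 0
  for (t in thresholds) {
    keep <- scores >= t
    n_tp <- sum(tp[keep]); n_fp <- sum(!tp[keep])
    p <- if (n_tp + n_fp > 0) n_tp / (n_tp + n_fp) else 0
    r <- n_tp / n_sites
    ap <- ap + (r - r_prev) * p
    r_prev <- r
  }
  ap
}
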