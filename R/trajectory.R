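#' Predict binding sites across a conformational ensemble
#'
#' Applies the detector to every frame of a pre-aligned ensemble
#' (molecular-dynamics frames, minimization snapshots, multi-model PDB
#' entries) and tags each frame's post-NMS predictions with its frame
#' index, yielding the prediction cloud that spatiotemporal clustering
#' consumes.
#'
#' @param frames List of `protein_structure` objects sharing a reference
#'   frame.
#' @param model A trained `site_detector`, or a function
#'   `function(structure, params)` returning a prediction tibble (useful
#'   for injecting deterministic scores in tests).
#' @param params An [nms_params()].
#' @param ... Passed on to [predict_sites()].
#' @return Tibble of predictions with a `frame` column; attribute
#'   `n_frames` records the ensemble length.
#' @export
predict_ensemble <- function(frames, model, params = nms_params(), ...) {
  if (length(frames) == 0) rlang::abort("empty ensemble")
  cloud <- purrr::map_dfr(seq_along(frames), function(f) {
    st <- frames[[f]]
    preds <- if (is.function(model)) model(st, params)
             else predict_sites(st, model, params, ...)
    preds$frame <- f
    preds
  })
  attr(cloud, "n_frames") <- length(frames)
  cloud
}

#' Cluster a prediction cloud
#'
#' Groups ensemble predictions into putative sites with one of three
#' algorithms: mean shift (flat kernel, modes merged within half a
#' bandwidth), DBSCAN (noise points become singleton clusters flagged
#' `noise`), or agglomerative hierarchical clustering with average
#' linkage, either on Cartesian centers or -- uniquely for the
#' agglomerative route -- on residue sets under 1 minus the Jaccard
#' index.
#'
#' @param cloud Prediction tibble (`x`, `y`, `z`, `score`, `frame`, and a
#'   `residues` list-column for Jaccard mode).
#' @param method `"meanshift"`, `"dbscan"`, or `"agglomerative"`.
#' @param bandwidth Mean-shift bandwidth, angstroms (default 8).
#' @param eps DBSCAN neighborhood radius, angstroms (default 4).
#' @param min_samples DBSCAN core-point minimum (default 5).
#' @param h Agglomerative cut height: angstroms in Cartesian mode, a
#'   Jaccard distance in residue mode (defaults 8 and 0.5).
#' @param on `"centers"` (Cartesian) or `"residues"` (agglomerative only).
#' @return `cloud` with `cluster` (integer) and `noise` (logical) columns.
#' @export
cluster_cloud <- function(cloud, method = c("meanshift", "dbscan",
                                            "agglomerative"),
                          bandwidth = 8, eps = 4, min_samples = 5L,
                          h = NULL, on = c("centers", "residues")) {
  method <- match.arg(method)
  on <- match.arg(on)
  if (nrow(cloud) == 0) rlang::abort("empty prediction cloud")
  if (on == "residues" && method != "agglomerative") {
    rlang::abort("residue-set clustering is only available for the agglomerative method")
  }
  xyz <- as.matrix(cloud[, c("x", "y", "z")])
  cl <- switch(method,
    meanshift = .mean_shift(xyz, bandwidth),
    dbscan = .dbscan(xyz, eps, min_samples),
    agglomerative = {
      if (on == "centers") {
        hgt <- h %||% 8
        if (nrow(xyz) == 1) list(cluster = 1L, noise = FALSE)
        else list(cluster = stats::cutree(
          stats::hclust(stats::dist(xyz), method = "average"), h = hgt),
          noise = FALSE)
      } else {
        hgt <- h %||% 0.5
        d <- .jaccard_dist(cloud$residues)
        if (nrow(xyz) == 1) list(cluster = 1L, noise = FALSE)
        else list(cluster = stats::cutree(
          stats::hclust(stats::as.dist(d), method = "average"), h = hgt),
          noise = FALSE)
      }
    }
  )
  cloud$cluster <- as.integer(cl$cluster)
  cloud$noise <- if (length(cl$noise) == 1) rep(cl$noise, nrow(cloud)) else cl$noise
  cloud
}

# flat-kernel mean shift seeded on every point; modes merged at bandwidth/2
.mean_shift <- function(xyz, bandwidth, max_iter = 100L, tol = 1e-4) {
  n <- nrow(xyz)
  modes <- xyz
  for (it in seq_len(max_iter)) {
    moved <- FALSE
    for (i in seq_len(n)) {
      d2 <- colSums((t(xyz) - modes[i, ])^2)
      nb <- d2 <= bandwidth^2
      new_mode <- colMeans(xyz[nb, , drop = FALSE])
      if (sum((new_mode - modes[i, ])^2) > tol^2) moved <- TRUE
      modes[i, ] <- new_mode
    }
    if (!moved) break
  }
  # merge modes closer than bandwidth / 2
  cluster <- integer(n)
  centers <- matrix(numeric(0), 0, 3)
  for (i in seq_len(n)) {
    if (nrow(centers) > 0) {
      d2 <- colSums((t(centers) - modes[i, ])^2)
      hit <- which(d2 <= (bandwidth / 2)^2)
    } else hit <- integer(0)
    if (length(hit) > 0) {
      cluster[i] <- hit[1]
    } else {
      centers <- rbind(centers, modes[i, ])
      cluster[i] <- nrow(centers)
    }
  }
  list(cluster = cluster, noise = rep(FALSE, n))
}

# classic DBSCAN on a dense distance matrix; noise -> singleton clusters
.dbscan <- function(xyz, eps, min_samples) {
  n <- nrow(xyz)
  d2 <- as.matrix(stats::dist(xyz))^2
  nb <- d2 <= eps^2
  core <- rowSums(nb) >= min_samples   # neighborhood includes the point
  cluster <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (cluster[i] != 0L || !core[i]) next
    cid <- cid + 1L
    queue <- i
    cluster[i] <- cid
    while (length(queue) > 0) {
      q <- queue[1]; queue <- queue[-1]
      if (core[q]) {
        for (j in which(nb[q, ])) {
          if (cluster[j] == 0L) {
            cluster[j] <- cid
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  noise <- cluster == 0L
  for (i in which(noise)) {
    cid <- cid + 1L
    cluster[i] <- cid
  }
  list(cluster = cluster, noise = noise)
}

.jaccard_dist <- function(residue_sets) {
  n <- length(residue_sets)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- residue_sets[[i]]; b <- residue_sets[[j]]
      u <- length(union(a, b))
      d[i, j] <- d[j, i] <- if (u == 0) 0 else 1 - length(intersect(a, b)) / u
    }
  }
  d
}

#' Score site clusters over an ensemble
#'
#' Two per-cluster scores summarize persistence and strength across
#' frames. Score 1 is the sum over all frames of the cluster's maximal
#' member score in that frame (0 where absent), divided by the total
#' number of frames. Score 2 takes, in each frame where the cluster has
#' members scoring above `step_threshold`, the sum of those member
#' scores, and averages these sums over the frames that contributed.
#'
#' @param clustered Output of [cluster_cloud()].
#' @param n_frames Total frames in the ensemble (defaults to the cloud's
#'   `n_frames` attribute).
#' @param step_threshold Score cutoff entering score 2 (default 0.1).
#' @return Tibble: `cluster`, `n_members`, `noise`, representative center
#'   (`cx`, `cy`, `cz` = member-center means), `score_max_avg`,
#'   `score_meansum_avg`.
#' @export
score_clusters <- function(clustered, n_frames = NULL, step_threshold = 0.1) {
  n_frames <- n_frames %||% attr(clustered, "n_frames") %||%
    max(clustered$frame)
  clustered |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      noise = any(.data$noise),
      cx = mean(.data$x), cy = mean(.data$y), cz = mean(.data$z),
      score_max_avg = {
        per_frame <- tapply(.data$score, .data$frame, max)
        sum(per_frame) / n_frames
      },
      score_meansum_avg = {
        keep <- .data$score > step_threshold
        if (!any(keep)) 0 else {
          sums <- tapply(.data$score[keep], .data$frame[keep], sum)
          mean(sums)
        }
      },
      .groups = "drop"
    )
}

#' Per-frame trace of cluster scores
#'
#' The maximal member score of each cluster in each frame, suitable for
#' plotting score-vs-frame curves for pocket opening/closing events.
#'
#' @param clustered Output of [cluster_cloud()].
#' @param n_frames Total frames (defaults to the cloud attribute).
#' @return Tibble: `frame`, `cluster`, `max_score` (0 where the cluster
#'   is absent from the frame).
#' @export
cluster_trace <- function(clustered, n_frames = NULL) {
  n_frames <- n_frames %||% attr(clustered, "n_frames") %||%
    max(clustered$frame)
  grid <- tidyr::expand_grid(frame = seq_len(n_frames),
                             cluster = sort(unique(clustered$cluster)))
  present <- clustered |>
    dplyr::group_by(.data$frame, .data$cluster) |>
    dplyr::summarise(max_score = max(.data$score), .groups = "drop")
  dplyr::left_join(grid, present, by = c("frame", "cluster")) |>
    dplyr::mutate(max_score = tidyr::replace_na(.data$max_score, 0))
}

#' Windowed mean RMSD along an ensemble
#'
#' Root-mean-square deviation of an atom selection from its position in a
#' reference frame, smoothed by averaging over a centered window of
#' frames -- a generic mobility trace for ligands, lipids, or binding-site
#' residues along a trajectory.
#'
#' @param frames List of `protein_structure` objects with identical atom
#'   ordering.
#' @param selection Logical or integer vector selecting atom rows.
#' @param reference Frame index used as reference (default 1).
#' @param window Half-width of the smoothing window in frames (default
#'   100); frame f averages raw RMSD over `[f - window, f + window]`
#'   clipped to the trajectory.
#' @return Tibble: `frame`, `rmsd` (raw), `rmsd_windowed`.
#' @export
windowed_rmsd <- function(frames, selection, reference = 1L, window = 100L) {
  ref <- as.matrix(frames[[reference]]$atoms[selection, c("x", "y", "z")])
  raw <- vapply(frames, function(st) {
    xyz <- as.matrix(st$atoms[selection, c("x", "y", "z")])
    sqrt(mean(rowSums((xyz - ref)^2)))
  }, numeric(1))
  n <- length(raw)
  smoothed <- vapply(seq_len(n), function(f) {
    lo <- max(1L, f - window); hi <- min(n, f + window)
    mean(raw[lo:hi])
  }, numeric(1))
  tibble::tibble(frame = seq_len(n), rmsd = raw, rmsd_windowed = smoothed)
}
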