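#' Matching criterion for scoring predictions
#'
#' A prediction is correct for a true site either when its center lies
#' within `d_threshold` of the site center (`mode = "center"`, the
#' training-time definition) or when its minimal distance to any ligand
#' heavy atom is below `d_threshold` (`mode = "ligand"`, used for
#' cross-method comparison).
#'
#' @param mode `"center"` or `"ligand"`.
#' @param d_threshold Distance threshold in angstroms (default 4.0).
#' @return A `match_criterion` object.
#' @export
match_criterion <- function(mode = c("center", "ligand"), d_threshold = 4.0) {
  mode <- match.arg(mode)
  if (d_threshold <= 0) rlang::abort("d_threshold must be positive")
  structure(list(mode = mode, d_threshold = d_threshold),
            class = "match_criterion")
}

#' Label predictions against true sites
#'
#' The top-scored correct prediction of each true site is its one true
#' positive; every other prediction is a false positive, and sites with
#' no correct prediction are false negatives. Matching is one-to-one and
#' greedy: predictions are visited in descending score order (ties by
#' coordinates) and claim the nearest still-unmatched site they satisfy
#' the criterion for.
#'
#' @param preds Prediction tibble (`x`, `y`, `z`, `score`).
#' @param sites Site tibble (`cx`, `cy`, `cz`; for ligand mode also a
#'   `ligand_xyz` list-column of ligand heavy-atom coordinate matrices).
#' @param crit A [match_criterion()].
#' @return A list: `labels` (preds with `tp` flag and `matched_site`
#'   index, ordered by descending score) and `n_fn` (unmatched sites).
#' @export
match_predictions <- function(preds, sites, crit = match_criterion()) {
  preds <- tibble::as_tibble(preds)
  n_sites <- if (is.null(sites)) 0L else nrow(sites)
  if (nrow(preds) == 0) {
    labels <- dplyr::mutate(preds, tp = logical(0),
                            matched_site = integer(0))
    return(list(labels = labels, n_fn = n_sites))
  }
  ord <- order(-preds$score, preds$x, preds$y, preds$z)
  preds <- preds[ord, , drop = FALSE]
  tp <- logical(nrow(preds))
  matched <- rep(NA_integer_, nrow(preds))
  site_taken <- rep(FALSE, n_sites)
  if (n_sites > 0) {
    for (i in seq_len(nrow(preds))) {
      ctr <- c(preds$x[i], preds$y[i], preds$z[i])
      d <- vapply(seq_len(n_sites), function(s) {
        if (crit$mode == "center") {
          sqrt(sum((ctr - c(sites$cx[s], sites$cy[s], sites$cz[s]))^2))
        } else {
          lig <- sites$ligand_xyz[[s]]
          min(sqrt(colSums((t(lig) - ctr)^2)))
        }
      }, numeric(1))
      ok <- which(!site_taken & d <= crit$d_threshold)
      if (length(ok) > 0) {
        s <- ok[which.min(d[ok])]
        tp[i] <- TRUE
        matched[i] <- s
        site_taken[s] <- TRUE
      }
    }
  }
  preds$tp <- tp
  preds$matched_site <- matched
  list(labels = preds, n_fn = sum(!site_taken))
}

#' Precision and recall from labeled predictions
#'
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)`; both are
#' defined as 0 when their denominator is 0, which keeps average
#' precision well-defined on empty outputs.
#'
#' @param n_tp,n_fp,n_fn Non-negative counts.
#' @return A list with `precision` and `recall`.
#' @export
precision_recall <- function(n_tp, n_fp, n_fn) {
  p <- if (n_tp + n_fp > 0) n_tp / (n_tp + n_fp) else 0
  r <- if (n_tp + n_fn > 0) n_tp / (n_tp + n_fn) else 0
  list(precision = p, recall = r)
}

#' Average precision of a ranked prediction list
#'
#' The area under the precision-recall curve as the score threshold
#' sweeps the ranked list, computed by interpolation-free step summation:
#' each true positive at rank k contributes `precision@k / n_sites`
#' (equivalently `sum(delta_recall * precision)`).
#'
#' @param tp_ranked Logical vector: TP labels in descending-score order.
#' @param n_sites Total number of true sites (> 0).
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(tp_ranked, n_sites) {
  if (n_sites <= 0) rlang::abort("average precision needs at least one true site")
  if (length(tp_ranked) == 0) return(0)
  cum_tp <- cumsum(tp_ranked)
  prec_at_k <- cum_tp / seq_along(tp_ranked)
  sum(prec_at_k[tp_ranked]) / n_sites
}

#' Evaluate predictions against ground truth
#'
#' Pools (optionally per-structure) predictions, labels them with
#' [match_predictions()], and reports counts, precision, recall, and
#' average precision. With `top_n`, each structure's predictions are first
#' truncated to its own number of true sites (the Top-N protocol).
#'
#' @param preds Prediction tibble with a `structure_id` column (any single
#'   id works for one structure).
#' @param sites Site tibble with a `structure_id` column.
#' @param crit A [match_criterion()].
#' @param top_n Truncate each structure's ranked predictions to its site
#'   count before pooling (default `FALSE`).
#' @return A `site_eval` object: counts, `precision`, `recall`, `ap`, and
#'   the pooled ranked labels.
#' @export
evaluate_predictions <- function(preds, sites, crit = match_criterion(),
                                 top_n = FALSE) {
  preds <- tibble::as_tibble(preds)
  sites <- tibble::as_tibble(sites)
  if (!("structure_id" %in% names(preds))) preds$structure_id <- 1L
  if (!("structure_id" %in% names(sites))) sites$structure_id <- 1L
  ids <- unique(c(preds$structure_id, sites$structure_id))
  labeled <- purrr::map(ids, function(id) {
    p <- dplyr::filter(preds, .data$structure_id == id)
    s <- dplyr::filter(sites, .data$structure_id == id)
    if (top_n && nrow(p) > nrow(s)) {
      ord <- order(-p$score, p$x, p$y, p$z)
      p <- p[ord[seq_len(nrow(s))], , drop = FALSE]
    }
    match_predictions(p, s, crit)
  })
  labels <- purrr::map_dfr(labeled, "labels")
  n_fn <- sum(purrr::map_int(labeled, "n_fn"))
  labels <- labels[order(-labels$score, labels$x, labels$y, labels$z), ,
                   drop = FALSE]
  n_tp <- sum(labels$tp)
  n_fp <- sum(!labels$tp)
  pr <- precision_recall(n_tp, n_fp, n_fn)
  n_sites <- nrow(sites)
  ap <- if (n_sites > 0) average_precision(labels$tp, n_sites) else NA_real_
  structure(
    list(n_tp = n_tp, n_fp = n_fp, n_fn = n_fn,
         precision = pr$precision, recall = pr$recall, ap = ap,
         n_sites = n_sites, criterion = crit, top_n = top_n,
         labels = labels),
    class = "site_eval"
  )
}

#' @export
print.site_eval <- function(x, ...) {
  cat(sprintf(
    "<site_eval> %s criterion (%.1f A)%s: TP %d, FP %d, FN %d | precision %.3f, recall %.3f, AP %.3f\n",
    x$criterion$mode, x$criterion$d_threshold,
    if (x$top_n) ", Top-N" else "", x$n_tp, x$n_fp, x$n_fn,
    x$precision, x$recall, x$ap))
  invisible(x)
}

#' Per-family average precision
#'
#' Computes AP separately for each protein family (user-supplied label
#' mapping, e.g. InterPro identifiers), keeping only families with at
#' least `min_count` structures.
#'
#' @param preds,sites As in [evaluate_predictions()], with `structure_id`.
#' @param families Tibble mapping `structure_id` to `family`.
#' @param crit A [match_criterion()].
#' @param min_count Minimum structures per reported family (default 20).
#' @param top_n Top-N truncation flag.
#' @return Tibble: `family`, `n_structures`, `n_sites`, `ap`.
#' @export
family_breakdown <- function(preds, sites, families,
                             crit = match_criterion(), min_count = 20L,
                             top_n = FALSE) {
  families <- tibble::as_tibble(families)
  counts <- dplyr::count(families, .data$family, name = "n_structures")
  keep <- counts$family[counts$n_structures >= min_count]
  purrr::map_dfr(keep, function(fam) {
    ids <- families$structure_id[families$family == fam]
    ev <- evaluate_predictions(
      dplyr::filter(preds, .data$structure_id %in% ids),
      dplyr::filter(sites, .data$structure_id %in% ids),
      crit, top_n = top_n)
    tibble::tibble(family = fam,
                   n_structures = sum(families$family == fam),
                   n_sites = ev$n_sites, ap = ev$ap)
  })
}
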