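#' Tidy a trained detector
#'
#' Returns the per-epoch training history, one row per epoch.
#'
#' @param x A `site_detector`.
#' @param ... Ignored.
#' @return A tibble (`epoch`, `loss`, `score_term`, `coord_term`,
#'   `l2_term`), or an empty tibble for an untrained model.
#' @exportS3Method generics::tidy
tidy.site_detector <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(0), loss = numeric(0),
                          score_term = numeric(0), coord_term = numeric(0),
                          l2_term = numeric(0)))
  }
  x$history
}

#' One-row summary of a trained detector
#'
#' @param x A `site_detector`.
#' @param ... Ignored.
#' @return A one-row tibble: architecture counts, parameter count, final
#'   training loss.
#' @exportS3Method generics::glance
glance.site_detector <- function(x, ...) {
  n_par <- sum(vapply(x$layers, function(ly) {
    length(ly$W) + length(ly$b) +
      if (!is.null(ly$bn)) length(ly$bn$gamma) + length(ly$bn$beta) else 0L
  }, numeric(1)))
  tibble::tibble(
    n_layers = length(x$layers),
    n_parameters = n_par,
    cube_size = x$config$cube_size,
    n_channels = x$config$n_channels,
    epochs_trained = if (is.null(x$history)) 0L else max(x$history$epoch),
    final_loss = if (is.null(x$history)) NA_real_ else
      utils::tail(x$history$loss, 1)
  )
}

#' Tidy an evaluation result
#'
#' One row per ranked prediction with its label and the running
#' precision/recall at that rank.
#'
#' @param x A `site_eval`.
#' @param ... Ignored.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.site_eval <- function(x, ...) {
  labels <- x$labels
  labels$rank <- seq_len(nrow(labels))
  cum_tp <- cumsum(labels$tp)
  labels$precision_at_k <- cum_tp / labels$rank
  labels$recall_at_k <- cum_tp / max(x$n_sites, 1)
  labels
}

#' One-row summary of an evaluation result
#'
#' @param x A `site_eval`.
#' @param ... Ignored.
#' @return A one-row tibble with counts, precision, recall, and AP.
#' @exportS3Method generics::glance
glance.site_eval <- function(x, ...) {
  tibble::tibble(n_tp = x$n_tp, n_fp = x$n_fp, n_fn = x$n_fn,
                 n_sites = x$n_sites, precision = x$precision,
                 recall = x$recall, ap = x$ap,
                 criterion = x$criterion$mode,
                 d_threshold = x$criterion$d_threshold, top_n = x$top_n)
}
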