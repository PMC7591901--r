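#' Precision-recall curve of an evaluation
#'
#' @param object A `site_eval`.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.site_eval <- function(object, ...) {
  labels <- object$labels
  cum_tp <- cumsum(labels$tp)
  df <- tibble::tibble(
    recall = cum_tp / max(object$n_sites, 1),
    precision = cum_tp / seq_len(nrow(labels))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh", color = "#2c7fb8") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Recall", y = "Precision",
      title = sprintf("Precision-recall (AP = %.3f)", object$ap)) +
    ggplot2::theme_minimal()
}

#' Training-loss curves of a detector
#'
#' @param object A trained `site_detector`.
#' @param ... Ignored.
#' @return A ggplot of the per-epoch loss terms.
#' @exportS3Method ggplot2::autoplot
autoplot.site_detector <- function(object, ...) {
  if (is.null(object$history)) rlang::abort("model has no training history")
  long <- tidyr::pivot_longer(object$history, -"epoch",
                              names_to = "term", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     color = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Epoch", y = "Loss (log scale)", color = NULL) +
    ggplot2::theme_minimal()
}

#' Cluster score traces along an ensemble
#'
#' Plots each cluster's per-frame maximal score (the curves used to watch
#' pockets open and close along a trajectory).
#'
#' @param clustered Output of [cluster_cloud()].
#' @param n_frames Total frames (defaults to the cloud attribute).
#' @return A ggplot.
#' @export
plot_cluster_trace <- function(clustered, n_frames = NULL) {
  tr <- cluster_trace(clustered, n_frames)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$frame, y = .data$max_score,
                                   color = factor(.data$cluster))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frame", y = "Max cluster score", color = "Cluster") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
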