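#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot tracked trajectories
#'
#' x-y view of all tracked cell trajectories, coloured by cell.
#'
#' @param object a `track_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.track_result <- function(object, ...) {
  tr <- object$tracks
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                   group = .data$cell_id,
                                   colour = factor(.data$cell_id %% 12))) +
    ggplot2::geom_path(alpha = 0.7, show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("%d cells over %d volumes (%s mode)",
                                  object$n_cells, object$n_time,
                                  object$config$mode)) +
    ggplot2::theme_minimal()
}

#' Plot a tracking-accuracy curve
#'
#' @param object an `accuracy_curve` from [accuracy_vs_truth()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.accuracy_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "volume", y = "fraction of cells tracked correctly") +
    ggplot2::theme_minimal()
}

#' Plot matcher training history
#'
#' @param object an `ffn_fit`.
#' @param ... unused.
#' @return A ggplot of loss and held-out accuracy per epoch.
#' @export
autoplot.ffn_fit <- function(object, ...) {
  h <- tidy.ffn_fit(object)
  long <- tidyr::pivot_longer(h, c("train_loss", "val_accuracy"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of relative movements
#'
#' @param rm RM tibble from [compute_rm()] or a `track_result`.
#' @param binwidth histogram bin width (default 0.05).
#' @return A ggplot with the 0.5 and 1.0 difficulty thresholds marked.
#' @export
plot_rm_distribution <- function(rm, binwidth = 0.05) {
  if (inherits(rm, "track_result")) rm <- rm$rm
  ggplot2::ggplot(rm, ggplot2::aes(x = .data$rm)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey40") +
    ggplot2::geom_vline(xintercept = c(0.5, 1), linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "relative movement (RM)", y = "movements") +
    ggplot2::theme_minimal()
}
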