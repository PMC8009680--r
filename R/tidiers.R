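#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a tracking result
#'
#' @param x a `track_result`.
#' @param ... unused.
#' @return The track table tibble
#'   (`cell_id, t, z_um, y_um, x_um, status, corrected`).
#' @export
tidy.track_result <- function(x, ...) x$tracks

#' @rdname tidy.track_result
#' @return `glance` returns a one-row tibble summarising the run: cell
#'   and volume counts, exited cells, median RM and the count of
#'   challenging movements.
#' @export
glance.track_result <- function(x, ...) {
  tibble::tibble(
    n_cells = x$n_cells,
    n_volumes = x$n_time,
    mode = x$config$mode,
    n_exited = length(unique(x$tracks$cell_id[x$tracks$status == "exited"])),
    median_rm = stats::median(x$rm$rm, na.rm = TRUE),
    n_rm_ge_05 = sum(x$rm$rm >= 0.5, na.rm = TRUE),
    n_rm_ge_10 = sum(x$rm$rm >= 1.0, na.rm = TRUE))
}

#' Tidy a trained matcher
#'
#' @param x an `ffn_fit`.
#' @param ... unused.
#' @return The per-epoch training history tibble.
#' @export
tidy.ffn_fit <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(0), train_loss = numeric(0),
                                val_accuracy = numeric(0))
}

#' @rdname tidy.ffn_fit
#' @export
glance.ffn_fit <- function(x, ...) {
  n_par <- length(x$W1) + length(x$b1) + length(x$W2) + length(x$b2) +
    length(x$W3) + 1 + 4 * x$hidden
  last <- if (!is.null(x$history) && nrow(x$history)) {
    x$history[nrow(x$history), ]
  } else tibble::tibble(train_loss = NA_real_, val_accuracy = NA_real_)
  tibble::tibble(hidden = x$hidden, n_parameters = n_par,
                 epochs = if (is.null(x$history)) 0L else nrow(x$history),
                 final_loss = last$train_loss,
                 holdout_accuracy = last$val_accuracy)
}

#' Tidy a fitted transformation
#'
#' @param x a `prgls_transform`.
#' @param ... unused.
#' @return Tibble of anchors and their displacement coefficients.
#' @export
tidy.prgls_transform <- function(x, ...) {
  tibble::tibble(anchor_z = x$anchors[, 1], anchor_y = x$anchors[, 2],
                 anchor_x = x$anchors[, 3],
                 coef_z = x$coefficients[, 1], coef_y = x$coefficients[, 2],
                 coef_x = x$coefficients[, 3])
}

#' @rdname tidy.prgls_transform
#' @export
glance.prgls_transform <- function(x, ...) {
  moved <- apply_transform(x, x$anchors)
  tibble::tibble(n_anchors = nrow(x$anchors), beta = x$beta,
                 sigma = sqrt(x$sigma2), iterations = x$n_iter,
                 mean_displacement = mean(sqrt(rowSums((moved - x$anchors)^2))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
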