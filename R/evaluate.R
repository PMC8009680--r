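#' Summary of challenging movements
#'
#' Counts, per cell and in total, the movements whose relative movement
#' (RM) exceeds the thresholds at which naive nearest-cell tracking
#' degrades (0.5) and fails outright (1.0).
#'
#' @param x a `track_result`, or an RM tibble from [compute_rm()].
#' @return Tibble with one row per cell (`cell_id`, `n_steps`,
#'   `n_rm_ge_05`, `n_rm_ge_10`) and attribute `"totals"`: a one-row
#'   tibble with total and per-cell counts.
#' @export
rm_stats <- function(x) {
  rm_tbl <- if (inherits(x, "track_result")) x$rm else x
  stopifnot(all(c("cell_id", "t", "rm") %in% names(rm_tbl)))
  if (length(unique(rm_tbl$t)) < 1) {
    stop("RM statistics require at least 2 time points", call. = FALSE)
  }
  per_cell <- rm_tbl |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(n_steps = dplyr::n(),
                     n_rm_ge_05 = sum(.data$rm >= 0.5, na.rm = TRUE),
                     n_rm_ge_10 = sum(.data$rm >= 1.0, na.rm = TRUE),
                     .groups = "drop")
  n_cells <- nrow(per_cell)
  totals <- tibble::tibble(
    total_movements = sum(per_cell$n_steps),
    total_rm_ge_05 = sum(per_cell$n_rm_ge_05),
    total_rm_ge_10 = sum(per_cell$n_rm_ge_10),
    per_cell_rm_ge_05 = sum(per_cell$n_rm_ge_05) / n_cells,
    per_cell_rm_ge_10 = sum(per_cell$n_rm_ge_10) / n_cells)
  attr(per_cell, "totals") <- totals
  per_cell
}

#' Tracking accuracy against ground truth
#'
#' Per volume, the fraction of cells whose tracked position is correct:
#' inside the cell's true labeled region when truth label volumes are
#' available, otherwise within half the cell's true nearest-neighbour
#' distance of the true position.
#'
#' @param tracks a `track_result` or track table tibble.
#' @param truth ground-truth track table (`cell_id, t, z_um, y_um, x_um`),
#'   e.g. `scene$truth_tracks`.
#' @param truth_labels optional list of true [label_volume()]s per time.
#' @return An `accuracy_curve` tibble `t, accuracy`.
#' @export
accuracy_vs_truth <- function(tracks, truth, truth_labels = NULL) {
  if (inherits(tracks, "track_result")) tracks <- tracks$tracks
  if (!setequal(unique(tracks$cell_id), unique(truth$cell_id))) {
    stop("tracked and truth cell_id spaces differ", call. = FALSE)
  }
  ts <- sort(unique(tracks$t))
  acc <- numeric(length(ts))
  for (k in seq_along(ts)) {
    tt <- ts[k]
    tr <- tracks[tracks$t == tt, ]
    tr <- tr[order(tr$cell_id), ]
    tu <- truth[truth$t == tt, ]
    tu <- tu[order(tu$cell_id), ]
    tm <- as.matrix(tr[, c("z_um", "y_um", "x_um")])
    um <- as.matrix(tu[, c("z_um", "y_um", "x_um")])
    ok <- logical(nrow(tm))
    lab <- if (!is.null(truth_labels) && length(truth_labels) >= tt)
      truth_labels[[tt]] else NULL
    if (!is.null(lab)) {
      sp <- spacing_of(lab)
      d <- dim(lab)
      vox <- pmin(pmax(round(sweep(tm, 2, sp, "/")) + 1, 1),
                  matrix(d, nrow(tm), 3, byrow = TRUE))
      inlab <- lab[vox] == tu$cell_id
      ok <- ok | inlab
    }
    nnd <- nn_distance(um)
    ok <- ok | (sqrt(rowSums((tm - um)^2)) < 0.5 * nnd)
    acc[k] <- mean(ok)
  }
  structure(tibble::tibble(t = ts, accuracy = acc),
            class = c("accuracy_curve", "tbl_df", "tbl", "data.frame"))
}

#' Extract fluorescence activity from tracked regions
#'
#' Per cell and time, the mean raw intensity of each requested channel
#' over the tracked region, and their ratio (e.g. GCaMP / tdTomato, or
#' FRET YFP / CFP). Always computed on raw intensities; contrast
#' normalization is a segmentation-only step.
#'
#' @param result a `track_result` with `labels` kept, or a list of
#'   per-time [label_volume()]s.
#' @param m the [movie()] holding the raw channels.
#' @param numerator_channel channel index for the activity reporter.
#' @param denominator_channel optional reference channel; when given the
#'   `ratio` column is numerator / denominator (NA when the denominator
#'   mean is not positive).
#' @return Tibble `cell_id, t, num_mean, den_mean, ratio, missing`.
#' @export
extract_activity <- function(result, m, numerator_channel = 2,
                             denominator_channel = 1) {
  labels <- if (inherits(result, "track_result")) result$labels else result
  if (is.null(labels)) {
    stop("tracked label volumes are required (run track_movie with keep_labels = TRUE)",
         call. = FALSE)
  }
  stopifnot(inherits(m, "movie"), numerator_channel <= m$n_channel)
  out <- vector("list", m$n_time)
  for (t in seq_len(m$n_time)) {
    if (t > length(labels)) next
    lab <- labels[[t]]
    if (is.null(lab)) next
    idx <- which(lab > 0L)
    l <- as.integer(lab[idx])
    ids <- sort(unique(l))
    nv <- tabulate(l)[ids]
    numv <- as.numeric(m$frames[[t]][[numerator_channel]])[idx]
    num_mean <- unname(rowsum(numv, l)[, 1]) / nv
    if (!is.null(denominator_channel)) {
      denv <- as.numeric(m$frames[[t]][[denominator_channel]])[idx]
      den_mean <- unname(rowsum(denv, l)[, 1]) / nv
      ratio <- ifelse(den_mean > 0, num_mean / den_mean, NA_real_)
    } else {
      den_mean <- NA_real_
      ratio <- NA_real_
    }
    out[[t]] <- tibble::tibble(cell_id = ids, t = t, num_mean = num_mean,
                               den_mean = den_mean, ratio = ratio,
                               missing = FALSE)
  }
  res <- dplyr::bind_rows(out)
  # flag cells absent from some volume's label image
  all_ids <- sort(unique(res$cell_id))
  full <- tidyr::expand_grid(cell_id = all_ids,
                             t = sort(unique(res$t)))
  res <- dplyr::left_join(full, res, by = c("cell_id", "t"))
  res$missing[is.na(res$missing)] <- TRUE
  res
}

#' Relative-movement boundary of nearest-cell assignment
#'
#' The one-dimensional two-cell demonstration of why relative movement
#' 0.5 is the critical difficulty: two cells sit a distance D apart;
#' cell A moves a distance m toward its neighbour B; each cell at the
#' new time is then assigned to the nearest cell of the previous time.
#' The sweep reports the smallest m / D at which cell A is captured by
#' B's previous identity (ties counted as failures).
#'
#' @param step grid resolution of the m / D sweep (default 0.001).
#' @return The smallest failing ratio (0.5 on any grid containing it).
#' @export
rm_failure_boundary <- function(step = 0.001) {
  D <- 1
  ratios <- seq(step, 1, by = step)
  for (r in ratios) {
    a1 <- 0; b1 <- D          # positions at t = 1
    a2 <- a1 + r * D          # A moves toward B; B stays
    # nearest-cell assignment of A's new position
    d_to_a <- abs(a2 - a1)
    d_to_b <- abs(a2 - b1)
    if (d_to_b <= d_to_a) return(r)
  }
  NA_real_
}

#' Cross-correlation phase lag between two periodic series
#'
#' Helper for oscillating tissues (e.g. beating-heart recordings): the
#' lag, in time steps, at which the cross-correlation of the two series
#' is largest. Dataset-specific; provided as an optional analysis.
#'
#' @param a,b numeric series of equal length.
#' @param max_lag largest lag examined (default a quarter of the length).
#' @return Integer lag (positive: `a` leads `b`).
#' @export
phase_lag <- function(a, b, max_lag = floor(length(a) / 4)) {
  stopifnot(length(a) == length(b), length(a) > 4)
  cc <- stats::ccf(a, b, lag.max = max_lag, plot = FALSE)
  cc$lag[which.max(cc$acf)]
}

#' Chamber-size proxy of a tracked cell population
#'
#' A robust volume proxy for a group of tracked cells:
#' `sd(x) * sd(y) * sd(z)` of their coordinates per time point.
#'
#' @param tracks track table tibble (already filtered to the cell group).
#' @return Tibble `t, size`.
#' @export
region_size_series <- function(tracks) {
  tracks |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(size = stats::sd(.data$x_um) * stats::sd(.data$y_um) *
                       stats::sd(.data$z_um), .groups = "drop")
}
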