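#' Tracker configuration
#'
#' Bundles the per-module parameters of the tracking pipeline.
#'
#' @param mode `"single"` (predict each volume from its predecessor) or
#'   `"ensemble"` (average up to `ensemble_max_refs` predictions from
#'   earlier reference volumes; more robust to large movements).
#' @param ensemble_max_refs maximum reference volumes averaged
#'   (default 20).
#' @param correction_max_iter iterations of the accurate-correction step
#'   (default 1; up to 20 for convergence on hard data).
#' @param correction_tol stop correction when the largest centre shift
#'   falls below this, micrometres (default 0.1).
#' @param interpolate_z evaluate correction centroids on a z-interpolated
#'   grid matching the x-y resolution (for strongly anisotropic data).
#' @param skip_volumes time indices to skip: cells are assumed not to
#'   have moved from the previous volume.
#' @param noise_level,window preprocessing parameters
#'   (see [local_contrast_normalize()]).
#' @param min_cell_size,blur_sigma segmentation parameters
#'   (see [instance_segment()]).
#' @param registration a [registration_params()].
#' @param min_match_score greedy-matching acceptance cutoff (default 0.5).
#' @param correction_target what the correction step pulls centres
#'   toward: `"prob_centroid"` (the probability-weighted centroid of
#'   overlapping cell-like voxels, the default) or `"region_centers"`
#'   (centres of the overlapped detected instance regions).
#' @param keep_labels retain the per-volume tracked label volumes in the
#'   result (needed for activity extraction; costs memory).
#' @return A `tracker_config` list.
#' @export
tracker_config <- function(mode = c("single", "ensemble"),
                           ensemble_max_refs = 20,
                           correction_max_iter = 1,
                           correction_tol = 0.1,
                           interpolate_z = FALSE,
                           skip_volumes = integer(0),
                           noise_level = 50,
                           window = c(27, 27, 3),
                           min_cell_size = 20,
                           blur_sigma = 1,
                           registration = registration_params(),
                           min_match_score = 0.5,
                           correction_target = c("prob_centroid", "region_centers"),
                           keep_labels = TRUE) {
  mode <- match.arg(mode)
  correction_target <- match.arg(correction_target)
  stopifnot(ensemble_max_refs >= 1, correction_max_iter >= 1,
            correction_tol > 0)
  structure(list(mode = mode, ensemble_max_refs = as.integer(ensemble_max_refs),
                 correction_max_iter = as.integer(correction_max_iter),
                 correction_tol = correction_tol,
                 interpolate_z = interpolate_z,
                 skip_volumes = as.integer(skip_volumes),
                 noise_level = noise_level, window = window,
                 min_cell_size = min_cell_size, blur_sigma = blur_sigma,
                 registration = registration,
                 min_match_score = min_match_score,
                 correction_target = correction_target,
                 keep_labels = keep_labels),
            class = "tracker_config")
}

#' Reference volumes for ensemble prediction
#'
#' For `t <= max_refs + 1` the references are all predecessors
#' `t-1, t-2, ..., 1`; beyond that they are `t-d, t-2d, ..., t-max_refs*d`
#' with `d = (t-1) %/% max_refs`, spreading up to `max_refs` references
#' evenly over the history.
#'
#' @param t time index (>= 2).
#' @param max_refs maximum number of references (default 20).
#' @return Integer vector of reference time indices, decreasing.
#' @export
ensemble_refs <- function(t, max_refs = 20) {
  if (t < 2) stop("ensemble references require t >= 2", call. = FALSE)
  t <- as.integer(t)
  max_refs <- as.integer(max_refs)
  # one reference reduces to single-mode behaviour (the quotient
  # schedule would degenerate to volume 1)
  if (max_refs == 1L) return(t - 1L)
  if (t - 1 <= max_refs) return(as.integer((t - 1):1))
  d <- (t - 1) %/% max_refs
  as.integer(t - d * seq_len(max_refs))
}

#' Predict cell positions in a new volume
#'
#' Scores all pairs between the reference positions and the detected
#' centres, forms the greedy initial matching, refines it into a coherent
#' transformation by [register()], and applies that transformation to the
#' reference positions. Output rows carry the reference cell ids.
#'
#' @param ref_positions tracked positions in the reference volume
#'   (tibble or matrix, >= 21 points).
#' @param detected detected cell centres in the new volume (>= 21 points).
#' @param ffn trained `ffn_fit`.
#' @param params a [registration_params()].
#' @param min_match_score greedy acceptance cutoff.
#' @return Matrix of predicted positions with ids.
#' @export
predict_positions <- function(ref_positions, detected, ffn,
                              params = registration_params(),
                              min_match_score = 0.5) {
  refm <- as_point_matrix(ref_positions)
  detm <- as_point_matrix(detected)
  scores <- score_pairs(ffn, refm, detm)
  init <- greedy_match(scores, min_match_score)
  rematcher <- if (!is.null(params$rematch_every)) {
    function(moved, B) {
      s <- score_pairs(ffn, moved, B)
      out <- greedy_match(s, min_match_score)
      attr(out, "scores") <- s
      out
    }
  } else NULL
  trans <- register(refm, detm, init, params, rematcher = rematcher,
                    scores = scores)
  apply_transform(trans, refm)
}

# Template regions from the first-volume segmentation: per cell, the voxel
# offsets (continuous, voxel units) relative to the region centroid.
template_regions <- function(labels_t1) {
  d <- dim(labels_t1)
  idx <- which(labels_t1 > 0L)
  l <- as.integer(labels_t1[idx])
  z <- (idx - 1L) %% d[1]
  y <- ((idx - 1L) %/% d[1]) %% d[2]
  x <- (idx - 1L) %/% (d[1] * d[2])
  ids <- sort(unique(l))
  split_i <- split(seq_along(l), l)
  lapply(split_i, function(ii) {
    off <- cbind(z[ii], y[ii], x[ii])
    sweep(off, 2, colMeans(off))
  })
}

#' Accurate correction of predicted positions
#'
#' Places each cell's first-volume template region at its predicted
#' centre and pulls the centre toward the probability-weighted centroid
#' of the cell-like voxels (probability > 0.5) overlapping the placed
#' region; repeats up to `correction_max_iter` times or until the largest
#' shift is below `correction_tol`. Cells whose placed regions overlap
#' are re-separated by a seeded watershed with the corrected centres as
#' seeds. With `interpolate_z`, centroids are evaluated on a z-refined
#' grid (trilinear interpolation) matching the x-y resolution.
#'
#' @param predicted predicted positions (matrix with ids, or tibble).
#' @param prob cell-probability [image_volume()] of the current volume.
#' @param template_labels the first-volume [label_volume()].
#' @param cfg a [tracker_config()].
#' @param templates precomputed template regions (internal reuse).
#' @param detected optional instance segmentation ([label_volume()]) of
#'   the current volume; when supplied, each centre is pulled toward the
#'   centres of the detected regions its placed template overlaps
#'   (weighted by overlap), instead of the raw probability centroid.
#' @return List: `positions` (matrix, ids), `labels` ([label_volume()]),
#'   `corrected` (logical: had overlapping cell-like voxels).
#' @export
accurate_correct <- function(predicted, prob, template_labels, cfg,
                             templates = NULL, detected = NULL) {
  pm <- as_point_matrix(predicted)
  ids <- attr(pm, "ids")
  d <- dim(prob)
  sp <- spacing_of(prob)
  pv <- unclass(prob); attributes(pv) <- list(dim = d)
  if (is.null(templates)) templates <- template_regions(template_labels)
  stopifnot(length(templates) >= length(ids))
  det_ctr <- NULL
  if (!is.null(detected)) {
    dc <- centers_of(detected, sp)
    det_ctr <- as.matrix(dc[, c("z_um", "y_um", "x_um")])
    rownames(det_ctr) <- dc$cell_id
  }
  extent <- (d - 1) * sp
  # clamp predictions into bounds
  for (ax in 1:3) pm[, ax] <- pmin(pmax(pm[, ax], 0), extent[ax])
  fine <- if (cfg$interpolate_z) max(1L, as.integer(round(sp[1] / sp[2]))) else 1L
  corrected <- rep(TRUE, nrow(pm))
  for (iter in seq_len(cfg$correction_max_iter)) {
    shift <- 0
    for (ci in seq_len(nrow(pm))) {
      tpl <- templates[[as.character(ids[ci])]]
      if (is.null(tpl)) tpl <- templates[[ci]]
      cvox <- pm[ci, ] / sp # 0-based continuous voxel coords
      if (fine > 1L) {
        zsub <- (seq_len(fine) - (fine + 1) / 2) / fine
        tplf <- tpl[rep(seq_len(nrow(tpl)), each = fine), , drop = FALSE]
        tplf[, 1] <- tplf[, 1] + zsub
        q <- sweep(tplf, 2, cvox, "+") + 1 # 1-based fractional
        w <- trilinear_at(pv, q)
        w[w <= 0.5] <- 0
        if (sum(w) <= 0) { corrected[ci] <- FALSE; next }
        pos_um <- sweep((q - 1), 2, sp, "*")
        d_own <- rowSums(sweep(pos_um, 2, pm[ci, ])^2)
        others <- setdiff(which(rowSums(sweep(pm, 2, pm[ci, ])^2) < 15^2), ci)
        if (length(others)) {
          d_min_other <- rep(Inf, nrow(pos_um))
          for (oj in others) {
            d_min_other <- pmin(d_min_other, rowSums(sweep(pos_um, 2, pm[oj, ])^2))
          }
          w[d_min_other < d_own] <- 0
          if (sum(w) <= 0) { corrected[ci] <- FALSE; next }
        }
        newc <- colSums((q - 1) * sp[col(q)] * w) / sum(w)
      } else {
        vox <- round(sweep(tpl, 2, cvox, "+")) + 1
        keep <- vox[, 1] >= 1 & vox[, 1] <= d[1] &
          vox[, 2] >= 1 & vox[, 2] <= d[2] &
          vox[, 3] >= 1 & vox[, 3] <= d[3]
        vox <- vox[keep, , drop = FALSE]
        if (nrow(vox) == 0) { corrected[ci] <- FALSE; next }
        if (!is.null(det_ctr)) {
          # pull toward the centres of the overlapped detected regions
          dl <- detected[vox]
          dl <- dl[dl > 0L]
          if (length(dl) == 0) { corrected[ci] <- FALSE; next }
          cnt <- table(dl)
          wts <- as.numeric(cnt)
          ctrs <- det_ctr[names(cnt), , drop = FALSE]
          newc <- colSums(ctrs * wts) / sum(wts)
        } else {
          w <- pv[vox]
          w[w <= 0.5] <- 0
          if (sum(w) <= 0) { corrected[ci] <- FALSE; next }
          # restrict the pull to this cell's own territory: voxels closer
          # (in physical distance) to another tracked centre contribute
          # nothing, so two cells sharing one blob keep to their own sides
          pos_um <- sweep((vox - 1), 2, sp, "*")
          d_own <- rowSums(sweep(pos_um, 2, pm[ci, ])^2)
          others <- which(rowSums(sweep(pm, 2, pm[ci, ])^2) < 15^2)
          others <- setdiff(others, ci)
          if (length(others)) {
            d_min_other <- rep(Inf, nrow(pos_um))
            for (oj in others) {
              d_min_other <- pmin(d_min_other,
                                  rowSums(sweep(pos_um, 2, pm[oj, ])^2))
            }
            w[d_min_other < d_own] <- 0
            if (sum(w) <= 0) { corrected[ci] <- FALSE; next }
          }
          newc <- colSums((vox - 1) * sp[col(vox)] * w) / sum(w)
        }
      }
      corrected[ci] <- TRUE
      shift <- max(shift, sqrt(sum((newc - pm[ci, ])^2)))
      pm[ci, ] <- pmin(pmax(newc, 0), extent)
    }
    if (shift < cfg$correction_tol) break
  }
  # rebuild the tracked label volume; resolve overlaps by seeded watershed
  lab <- array(0L, d)
  claimed <- array(0L, d)
  for (ci in seq_len(nrow(pm))) {
    tpl <- templates[[as.character(ids[ci])]]
    if (is.null(tpl)) tpl <- templates[[ci]]
    vox <- round(sweep(tpl, 2, pm[ci, ] / sp, "+")) + 1
    keep <- vox[, 1] >= 1 & vox[, 1] <= d[1] &
      vox[, 2] >= 1 & vox[, 2] <= d[2] &
      vox[, 3] >= 1 & vox[, 3] <= d[3]
    vox <- vox[keep, , drop = FALSE]
    if (nrow(vox) == 0) next
    li <- (vox[, 3] - 1L) * d[1] * d[2] + (vox[, 2] - 1L) * d[1] + vox[, 1]
    li <- unique(li)
    claimed[li] <- claimed[li] + 1L
    lab[li] <- ids[ci]
  }
  if (any(claimed > 1L)) {
    mask <- as.integer(claimed > 0L)
    seeds <- integer(prod(d))
    for (ci in seq_len(nrow(pm))) {
      cv <- pmin(pmax(round(pm[ci, ] / sp) + 1, 1), d)
      si <- (cv[3] - 1) * d[1] * d[2] + (cv[2] - 1) * d[1] + cv[1]
      seeds[si] <- ids[ci]
      mask[si] <- 1L
    }
    dist <- cpp_edt3d(mask, d, sp)
    bl <- gaussian_blur_3d(array(dist, d), rep(cfg$blur_sigma, 3))
    ws <- cpp_watershed(as.numeric(bl), mask, seeds, d, FALSE)
    lab <- array(as.integer(ws), d)
  }
  attr(pm, "ids") <- ids
  list(positions = pm, labels = label_volume(lab, sp), corrected = corrected)
}

#' Track a movie
#'
#' Runs the full per-volume tracking loop: segment each volume
#' (normalize, classify, watershed), predict the tracked cells' new
#' positions from one or several reference volumes (single or ensemble
#' mode), snap them onto the detected cell-like regions
#' ([accurate_correct()]), and accumulate the track table and
#' relative-movement record. Volumes listed in `skip_volumes` are carried
#' forward unchanged. Cells whose corrected centre leaves the volume are
#' flagged `exited` and frozen.
#'
#' @param m a [movie()] (channel 1: nuclear marker).
#' @param labels_t1 manually confirmed [label_volume()] of volume 1;
#'   its regions define the tracked identities.
#' @param clf trained `voxel_classifier`.
#' @param ffn trained `ffn_fit`.
#' @param cfg a [tracker_config()].
#' @param verbose print per-volume progress.
#' @return A `track_result`: `tracks` tibble
#'   (`cell_id, t, z_um, y_um, x_um, status, corrected`), `rm` tibble
#'   (`cell_id, t, rm`), `labels` (list of per-volume tracked label
#'   volumes when `keep_labels`), `config`.
#' @export
track_movie <- function(m, labels_t1, clf, ffn, cfg = tracker_config(),
                        verbose = FALSE) {
  stopifnot(inherits(m, "movie"), m$n_time >= 2)
  sp <- m$spacing
  ctr <- centers_of(labels_t1, sp)
  n_cells <- nrow(ctr)
  if (n_cells < 21) {
    stop("tracking requires at least 21 cells in the first volume", call. = FALSE)
  }
  templates <- template_regions(labels_t1)
  pos <- vector("list", m$n_time)
  pos[[1]] <- as_point_matrix(ctr)
  status <- matrix("tracked", n_cells, m$n_time)
  corrected <- matrix(TRUE, n_cells, m$n_time)
  labels_out <- if (cfg$keep_labels) vector("list", m$n_time) else NULL
  if (cfg$keep_labels) labels_out[[1]] <- labels_t1
  exited <- rep(FALSE, n_cells)
  extent <- (m$shape - 1) * sp
  for (t in 2:m$n_time) {
    if (t %in% cfg$skip_volumes) {
      pos[[t]] <- pos[[t - 1]]
      status[, t] <- ifelse(exited, "exited", "carried_forward")
      if (cfg$keep_labels) labels_out[[t]] <- labels_out[[t - 1]]
      next
    }
    vol <- movie_frame(m, t, 1)
    norm <- local_contrast_normalize(vol, cfg$noise_level, cfg$window)
    prob <- predict_probability(clf, norm)
    seg <- instance_segment(prob, cfg$min_cell_size, cfg$blur_sigma)
    det <- tryCatch(centers_of(seg, sp), error = function(e) {
      stop(sprintf("no cells detected in volume %d", t), call. = FALSE)
    })
    if (nrow(det) < 21) {
      stop(sprintf("fewer than 21 cells detected in volume %d", t), call. = FALSE)
    }
    refs <- if (cfg$mode == "single") t - 1L else ensemble_refs(t, cfg$ensemble_max_refs)
    refs <- refs[!(refs %in% cfg$skip_volumes) | refs == 1L]
    if (length(refs) == 0) refs <- t - 1L
    pred_sum <- matrix(0, n_cells, 3)
    pred_n <- numeric(n_cells)
    for (r in refs) {
      pr <- predict_positions(pos[[r]], det, ffn, cfg$registration,
                              cfg$min_match_score)
      use <- !exited
      pred_sum[use, ] <- pred_sum[use, ] + pr[use, , drop = FALSE]
      pred_n[use] <- pred_n[use] + 1
    }
    pred <- pos[[t - 1]]
    upd <- pred_n > 0
    pred[upd, ] <- pred_sum[upd, , drop = FALSE] / pred_n[upd]
    attr(pred, "ids") <- attr(pos[[1]], "ids")
    det_lab <- if (identical(cfg$correction_target, "region_centers")) seg else NULL
    ac <- accurate_correct(pred, prob, labels_t1, cfg, templates = templates,
                           detected = det_lab)
    newpos <- ac$positions
    # exit handling: freeze cells pushed to the volume border
    out_now <- apply(newpos, 1, function(p) any(p <= 0 - 1e-9) ||
                       any(p >= extent + 1e-9))
    newly_exited <- out_now & !exited
    exited <- exited | newly_exited
    newpos[exited, ] <- pos[[t - 1]][exited, , drop = FALSE]
    pos[[t]] <- newpos
    status[, t] <- ifelse(exited, "exited", "tracked")
    corrected[, t] <- ac$corrected
    if (cfg$keep_labels) labels_out[[t]] <- ac$labels
    if (verbose) {
      message(sprintf("volume %d: %d detected, %d tracked, %d exited",
                      t, nrow(det), sum(!exited), sum(exited)))
    }
  }
  tracks <- dplyr::bind_rows(lapply(seq_len(m$n_time), function(tt) {
    p <- pos[[tt]]
    tibble::tibble(cell_id = attr(pos[[1]], "ids"), t = tt,
                   z_um = p[, 1], y_um = p[, 2], x_um = p[, 3],
                   status = status[, tt], corrected = corrected[, tt])
  }))
  rm_tbl <- compute_rm(tracks)
  structure(list(tracks = tracks, rm = rm_tbl, labels = labels_out,
                 config = cfg, n_cells = n_cells, n_time = m$n_time),
            class = "track_result")
}

#' Relative movement (RM) per cell and time step
#'
#' `RM(cell, t) = ||movement from t-1 to t|| / (distance from the cell to
#' its nearest neighbouring cell at t)`; movements with RM >= 0.5 defeat
#' naive nearest-cell tracking. Undefined at t = 1.
#'
#' @param tracks a track table tibble (`cell_id, t, z_um, y_um, x_um`) or
#'   a `track_result`.
#' @return Tibble `cell_id, t, rm` for t >= 2.
#' @export
compute_rm <- function(tracks) {
  if (inherits(tracks, "track_result")) tracks <- tracks$tracks
  ts <- sort(unique(tracks$t))
  out <- vector("list", length(ts))
  prev <- NULL
  for (k in seq_along(ts)) {
    cur <- tracks[tracks$t == ts[k], ]
    cur <- cur[order(cur$cell_id), ]
    mat <- as.matrix(cur[, c("z_um", "y_um", "x_um")])
    if (!is.null(prev)) {
      mv <- sqrt(rowSums((mat - prev)^2))
      nnd <- nn_distance(mat)
      out[[k]] <- tibble::tibble(cell_id = cur$cell_id, t = ts[k],
                                 rm = mv / nnd)
    }
    prev <- mat
  }
  dplyr::bind_rows(out)
}

#' @export
print.track_result <- function(x, ...) {
  n_exited <- length(unique(x$tracks$cell_id[x$tracks$status == "exited"]))
  cat(sprintf("<track_result> %d cells x %d volumes (%s mode); %d exited\n",
              x$n_cells, x$n_time, x$config$mode, n_exited))
  if (nrow(x$rm)) {
    cat(sprintf("  RM: median %.3f, %d movements with RM >= 0.5\n",
                stats::median(x$rm$rm, na.rm = TRUE),
                sum(x$rm$rm >= 0.5, na.rm = TRUE)))
  }
  invisible(x)
}
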