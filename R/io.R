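#' Read and write volumes as multi-page TIFF
#'
#' Volumes are stored one 2D page per z plane. Intensity volumes are
#' written as 16-bit TIFF (values are clipped to `[0, 65535]`); label
#' volumes likewise (up to 65535 cells).
#'
#' @param vol an [image_volume()] or [label_volume()].
#' @param path file path.
#' @return `write_*` return the path invisibly; `read_*` return the
#'   volume.
#' @export
write_volume_tiff <- function(vol, path) {
  d <- dim(vol)
  pages <- lapply(seq_len(d[1]), function(z) {
    m <- matrix(as.numeric(vol[z, , ]), d[2], d[3])
    pmin(pmax(m, 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' @rdname write_volume_tiff
#' @param spacing voxel spacing `(z, y, x)` micrometres to attach.
#' @export
read_volume_tiff <- function(path, spacing) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1]]))
  a <- array(0, d)
  for (z in seq_len(d[1])) a[z, , ] <- pages[[z]]
  image_volume(a, spacing)
}

#' @rdname write_volume_tiff
#' @export
write_label_tiff <- function(vol, path) {
  if (max(vol) > 65535) stop("more than 65535 labels", call. = FALSE)
  write_volume_tiff(vol, path)
}

#' @rdname write_volume_tiff
#' @export
read_label_tiff <- function(path, spacing) {
  v <- read_volume_tiff(path, spacing)
  a <- round(unclass(v))
  attributes(a) <- list(dim = dim(v))
  label_volume(array(as.integer(a), dim(v)), spacing)
}

#' Read a 3D+T movie from TIFF files
#'
#' Accepts the two common layouts: one multi-page TIFF per time point and
#' channel (`<name>_t0001_c1.tif`, pages = z planes), or one single-page
#' TIFF per (time, z, channel) (`<name>_t0001_z01_c1.tif`). Channel tags
#' are optional (a single channel is assumed).
#'
#' @param dir directory holding the files.
#' @param spacing voxel spacing `(z, y, x)` micrometres.
#' @param name optional file-name prefix filter.
#' @return A [movie()].
#' @export
read_movie <- function(dir, spacing, name = NULL) {
  files <- list.files(dir, pattern = "\\.tiff?$", full.names = TRUE)
  if (!is.null(name)) files <- files[startsWith(basename(files), name)]
  if (length(files) == 0) stop("no TIFF files found", call. = FALSE)
  bn <- basename(files)
  tm <- regmatches(bn, regexpr("_t\\d+", bn))
  if (length(tm) != length(bn)) {
    stop("file names must carry a _t#### time tag", call. = FALSE)
  }
  tidx <- as.integer(sub("_t", "", tm))
  cm <- regmatches(bn, regexpr("_c\\d+", bn))
  cidx <- rep(1L, length(bn))
  has_c <- grepl("_c\\d+", bn)
  cidx[has_c] <- as.integer(sub("_c", "", regmatches(bn, regexpr("_c\\d+", bn))))
  zm <- grepl("_z\\d+", bn)
  zidx <- rep(NA_integer_, length(bn))
  zidx[zm] <- as.integer(sub("_z", "", regmatches(bn, regexpr("_z\\d+", bn))))
  ts <- sort(unique(tidx))
  chs <- sort(unique(cidx))
  per_plane <- any(zm)
  frames <- vector("list", length(ts))
  ref_shape <- NULL
  for (k in seq_along(ts)) {
    t <- ts[k]
    frames[[k]] <- vector("list", length(chs))
    for (c in seq_along(chs)) {
      sel <- tidx == t & cidx == chs[c]
      if (!any(sel)) {
        stop(sprintf("missing volume: t%04d channel %d", t, chs[c]), call. = FALSE)
      }
      if (per_plane) {
        zs <- sort(unique(zidx[!is.na(zidx)]))
        pages <- vector("list", length(zs))
        for (zi in seq_along(zs)) {
          f <- files[sel & zidx == zs[zi]]
          if (length(f) != 1) {
            stop(sprintf("missing plane: t%04d ... z%d", t, zs[zi]), call. = FALSE)
          }
          p <- tiff::readTIFF(f, as.is = TRUE)
          pages[[zi]] <- p
        }
        a <- array(0, c(length(pages), dim(pages[[1]])))
        for (z in seq_along(pages)) a[z, , ] <- pages[[z]]
      } else {
        f <- files[sel]
        if (length(f) != 1) {
          stop(sprintf("expected one stack for t%04d channel %d, found %d",
                       t, chs[c], length(f)), call. = FALSE)
        }
        a <- unclass(read_volume_tiff(f, spacing))
        attributes(a) <- list(dim = dim(a))
      }
      if (is.null(ref_shape)) ref_shape <- dim(a)
      if (!identical(dim(a), ref_shape)) {
        stop(sprintf("inconsistent shape in t%04d channel %d", t, chs[c]),
             call. = FALSE)
      }
      frames[[k]][[c]] <- a
    }
  }
  movie(frames, spacing)
}

#' @rdname read_movie
#' @param m a [movie()] to write.
#' @param name file-name prefix.
#' @return `write_movie` returns the written paths invisibly.
#' @export
write_movie <- function(m, dir, name = "movie") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (t in seq_len(m$n_time)) {
    for (c in seq_len(m$n_channel)) {
      p <- file.path(dir, sprintf("%s_t%04d_c%d.tif", name, t, c))
      write_volume_tiff(image_volume(m$frames[[t]][[c]], m$spacing), p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Track tables on disk
#'
#' CSV with columns `cell_id,t,z_um,y_um,x_um,status`. On disk the time
#' index is 0-based (volume #1 has `t = 0`); in R it is 1-based.
#'
#' @param tracks track table tibble or `track_result`.
#' @param path CSV path.
#' @export
write_tracks_csv <- function(tracks, path) {
  if (inherits(tracks, "track_result")) tracks <- tracks$tracks
  out <- tracks
  out$t <- out$t - 1L
  utils::write.csv(out[, intersect(c("cell_id", "t", "z_um", "y_um", "x_um",
                                     "status"), names(out))],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  out$t <- out$t + 1L
  out
}

#' Run configuration files
#'
#' YAML configuration mirroring the pipeline's parameter blocks
#' (`preprocess`: noise_level, window; `segment`: min_cell_size, backend,
#' blur_sigma; `track`: mode, beta, lambda, max_iter, rematch_every,
#' ensemble_max_refs, correction_max_iter, correction_tol, interpolate_z,
#' skip_volumes, min_match_score; plus `spacing`, `seed`, `paths`,
#' `output`). Unknown keys are rejected, all violations reported at once.
#'
#' @param path YAML file.
#' @return Validated configuration list (class `run_config`).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- list(
    preprocess = c("noise_level", "window"),
    segment = c("min_cell_size", "backend", "blur_sigma", "patch_shape"),
    track = c("mode", "beta", "lambda", "max_iter", "rematch_every",
              "ensemble_max_refs", "correction_max_iter", "correction_tol",
              "interpolate_z", "skip_volumes", "min_match_score"),
    top = c("preprocess", "segment", "track", "spacing", "seed", "paths",
            "output"))
  errs <- character(0)
  unknown_top <- setdiff(names(cfg), allowed$top)
  if (length(unknown_top)) {
    errs <- c(errs, sprintf("unknown top-level key(s): %s",
                            paste(unknown_top, collapse = ", ")))
  }
  for (blk in c("preprocess", "segment", "track")) {
    if (!is.null(cfg[[blk]])) {
      unk <- setdiff(names(cfg[[blk]]), allowed[[blk]])
      if (length(unk)) {
        errs <- c(errs, sprintf("unknown %s key(s): %s", blk,
                                paste(unk, collapse = ", ")))
      }
    }
  }
  if (!is.null(cfg$preprocess$noise_level) && cfg$preprocess$noise_level <= 0) {
    errs <- c(errs, "preprocess.noise_level must be positive")
  }
  if (!is.null(cfg$segment$min_cell_size) && cfg$segment$min_cell_size < 1) {
    errs <- c(errs, "segment.min_cell_size must be >= 1")
  }
  if (length(errs)) {
    stop(paste(c("invalid configuration:", errs), collapse = "\n  "),
         call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' @rdname read_config
#' @param cfg a `run_config`.
#' @return `as_tracker_config` returns the corresponding
#'   [tracker_config()].
#' @export
as_tracker_config <- function(cfg) {
  tr <- cfg$track %||% list()
  reg <- registration_params(
    beta = tr$beta %||% 20,
    lam = tr$lambda %||% 0.01,
    max_iter = tr$max_iter %||% 20,
    rematch_every = tr$rematch_every)
  tracker_config(
    mode = tr$mode %||% "single",
    ensemble_max_refs = tr$ensemble_max_refs %||% 20,
    correction_max_iter = tr$correction_max_iter %||% 1,
    correction_tol = tr$correction_tol %||% 0.1,
    interpolate_z = isTRUE(tr$interpolate_z),
    skip_volumes = tr$skip_volumes %||% integer(0),
    noise_level = cfg$preprocess$noise_level %||% 50,
    window = cfg$preprocess$window %||% c(27, 27, 3),
    min_cell_size = cfg$segment$min_cell_size %||% 20,
    blur_sigma = cfg$segment$blur_sigma %||% 1,
    registration = reg,
    min_match_score = tr$min_match_score %||% 0.5)
}

#' Save / load trained models
#'
#' Classifier and matcher states are stored as single RDS archives.
#'
#' @param object a `voxel_classifier` or `ffn_fit`.
#' @param path file path.
#' @export
save_model <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
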