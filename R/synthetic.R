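#' Parameters for simulated point-set deformations
#'
#' Matched training point sets are produced from one segmented base set by
#' a random near-identity affine map plus two uniform noise terms:
#' `x' = (I + U) x + e1 + e2` on mean-removed coordinates, with `U`
#' elementwise uniform on `(-affine_half_width, +affine_half_width)`,
#' `e1` a small per-point jitter, and `e2` a large displacement applied to
#' a random subset of points to mimic serious segmentation errors.
#'
#' @param affine_half_width half-width of the uniform distribution of the
#'   affine perturbation entries (unitless, default 0.05).
#' @param small_noise_half_width half-width of the per-point jitter in the
#'   point set's coordinate units (default 2).
#' @param large_noise_half_width half-width of the large-displacement term
#'   (default 5).
#' @param n_large_noise_points number of points receiving the large term
#'   (default 20, as for a 175-cell base set).
#' @param positive_fraction fraction of emitted pairs that are corresponding
#'   (same cell); the rest pair a point with an adjacent cell's image.
#' @param n_adjacent how many nearest neighbours count as "adjacent" when
#'   drawing the negative pair's cell (default 3; 1 restricts negatives
#'   to the single hardest neighbour).
#' @param seed integer seed for reproducible generation (NULL: use the
#'   current RNG stream).
#' @return A `pair_gen_params` list.
#' @export
pair_gen_params <- function(affine_half_width = 0.05,
                            small_noise_half_width = 2,
                            large_noise_half_width = 5,
                            n_large_noise_points = 20,
                            positive_fraction = 0.5,
                            n_adjacent = 3L,
                            seed = NULL) {
  stopifnot(affine_half_width >= 0, small_noise_half_width >= 0,
            large_noise_half_width >= 0, n_large_noise_points >= 0,
            positive_fraction >= 0, positive_fraction <= 1, n_adjacent >= 1)
  structure(list(affine_half_width = affine_half_width,
                 small_noise_half_width = small_noise_half_width,
                 large_noise_half_width = large_noise_half_width,
                 n_large_noise_points = as.integer(n_large_noise_points),
                 positive_fraction = positive_fraction,
                 n_adjacent = as.integer(n_adjacent),
                 seed = seed),
            class = "pair_gen_params")
}

#' Apply one random simulated deformation to a point set
#'
#' @param base point set (matrix or data frame; see Details of
#'   [generate_training_pairs()]).
#' @param params a [pair_gen_params()] object.
#' @return List with `points` (transformed, mean-removed coordinates),
#'   `base_centered`, `affine` (the 3x3 matrix `I + U`), and `large_idx`
#'   (indices that received the large noise term). Uses the current RNG
#'   stream (seed the caller for reproducibility).
#' @export
deform_point_set <- function(base, params = pair_gen_params()) {
  m <- as_point_matrix(base)
  n <- nrow(m)
  if (params$n_large_noise_points > n) {
    stop("n_large_noise_points exceeds the point-set size", call. = FALSE)
  }
  ctr <- colMeans(m)
  xc <- sweep(m, 2, ctr)
  U <- matrix(stats::runif(9, -params$affine_half_width, params$affine_half_width), 3, 3)
  A <- diag(3) + U
  e1 <- matrix(stats::runif(3 * n, -params$small_noise_half_width,
                            params$small_noise_half_width), n, 3)
  e2 <- matrix(0, n, 3)
  large_idx <- integer(0)
  if (params$n_large_noise_points > 0) {
    large_idx <- sort(sample.int(n, params$n_large_noise_points))
    e2[large_idx, ] <- stats::runif(3 * length(large_idx),
                                    -params$large_noise_half_width,
                                    params$large_noise_half_width)
  }
  pts <- xc %*% t(A) + e1 + e2
  colnames(pts) <- c("z", "y", "x")
  attr(pts, "ids") <- attr(m, "ids")
  list(points = pts, base_centered = xc, affine = A, large_idx = large_idx)
}

#' Generate labeled training pairs from simulated deformations
#'
#' Creates feature pairs for training the point-matching network. Each
#' deformed copy of the base set contributes `pairs_per_set` pairs: a
#' positive pair couples a transformed point A with its own base point B;
#' a negative pair couples B with the transformed image of one of B's
#' adjacent cells (drawn among its `n_adjacent` nearest neighbours).
#' Exactly `round(positive_fraction * n_pairs)` pairs are positive.
#'
#' @param base base point set: n x 3 matrix or data frame with columns
#'   `z/y/x` (or `z_um/y_um/x_um`), n >= 21.
#' @param params a [pair_gen_params()].
#' @param n_pairs total number of pairs to emit.
#' @param pairs_per_set pairs drawn per deformed set (default 360; the
#'   number of deformed sets is then `ceiling(n_pairs / pairs_per_set)`).
#' @return A tibble with columns `pair_id`, `set_id`, `label` (1 = same
#'   cell) and 61-column matrix columns `feature_a`, `feature_b`.
#' @export
generate_training_pairs <- function(base, params = pair_gen_params(),
                                    n_pairs, pairs_per_set = 360) {
  m <- as_point_matrix(base)
  n <- nrow(m)
  if (n < 21) stop("base point set requires at least 21 points", call. = FALSE)
  if (params$n_large_noise_points > n) {
    stop("n_large_noise_points exceeds the point-set size", call. = FALSE)
  }
  stopifnot(n_pairs >= 1, pairs_per_set >= 1)
  with_seed(params$seed, {
    xc <- sweep(m, 2, colMeans(m))
    feats_base <- build_features_all(xc)
    # adjacent cells of each point: its n_adjacent nearest neighbours
    # (negatives sample uniformly among them; ties broken by index)
    d2b <- cross_dist2(xc, xc)
    diag(d2b) <- Inf
    k_adj <- min(params$n_adjacent, n - 1L)
    adj <- t(apply(d2b, 1, function(r) order(r)[seq_len(k_adj)]))
    n_pos <- round(params$positive_fraction * n_pairs)
    labels <- integer(n_pairs)
    if (n_pos > 0) labels[sample.int(n_pairs, n_pos)] <- 1L
    fa <- matrix(NA_real_, n_pairs, 61)
    fb <- matrix(NA_real_, n_pairs, 61)
    set_id <- integer(n_pairs)
    done <- 0L
    set <- 0L
    while (done < n_pairs) {
      set <- set + 1L
      take <- min(pairs_per_set, n_pairs - done)
      def <- deform_point_set(m, params)
      feats_trans <- build_features_all(def$points)
      b_idx <- sample.int(n, take, replace = TRUE)
      rows <- done + seq_len(take)
      pick <- sample.int(k_adj, take, replace = TRUE)
      a_idx <- ifelse(labels[rows] == 1L, b_idx, adj[cbind(b_idx, pick)])
      fa[rows, ] <- feats_trans[a_idx, , drop = FALSE]
      fb[rows, ] <- feats_base[b_idx, , drop = FALSE]
      set_id[rows] <- set
      done <- done + take
    }
    tibble::tibble(pair_id = seq_len(n_pairs), set_id = set_id,
                   label = labels, feature_a = fa, feature_b = fb)
  })
}

#' Parameters of a synthetic 3D+T scene
#'
#' Defines a volumetric two-channel movie of moving nuclear blobs with
#' full ground truth. Nuclei are anisotropic Gaussian blobs on a constant
#' background with Poisson shot noise; per time step they are carried by
#' a smooth (coherence-length-filtered) random displacement field, so
#' nearby cells move together, as in a deforming tissue. A second channel
#' shares the nuclear geometry with an independent per-cell activity
#' time course, emulating a co-expressed activity reporter.
#'
#' @param n_cells number of nuclei (default 150).
#' @param volume_shape voxels `(z, y, x)` (default `c(16, 192, 192)`).
#' @param spacing micrometres per voxel `(z, y, x)` (default `c(2, 0.5, 0.5)`,
#'   the usual confocal anisotropy).
#' @param cell_radius mean and sd of nuclear radius in micrometres
#'   (default `c(2, 0.3)`).
#' @param deformation_amplitude median per-step displacement magnitude in
#'   micrometres (default 2.6, about 0.3x the typical nearest-neighbour
#'   distance at these densities).
#' @param deformation_coherence_length Gaussian correlation length of the
#'   displacement field in micrometres (default 20).
#' @param reversion_rate per-step elastic pull of each cell back toward
#'   its reference position (default 0.15): deformations stay bounded
#'   around the initial configuration, as in a bending worm or a beating
#'   heart, instead of diffusing apart.
#' @param intensity_cell peak nuclear amplitude above background, in counts
#'   (default 300).
#' @param intensity_bg background level in counts (default 100).
#' @param photobleach_rate per-volume fractional intensity loss (default 0).
#' @param n_volumes number of time points (default 50).
#' @param activity_channel render the second (activity) channel
#'   (default TRUE).
#' @param truth_labels_at `"all"`, or integer time indices at which to keep
#'   ground-truth label volumes (label volumes are large).
#' @param seed integer seed.
#' @return A `scene_params` list.
#' @export
scene_params <- function(n_cells = 150,
                         volume_shape = c(16, 192, 192),
                         spacing = c(2, 0.5, 0.5),
                         cell_radius = c(2, 0.3),
                         deformation_amplitude = 2.6,
                         deformation_coherence_length = 20,
                         reversion_rate = 0.15,
                         intensity_cell = 300,
                         intensity_bg = 100,
                         photobleach_rate = 0,
                         n_volumes = 50,
                         activity_channel = TRUE,
                         truth_labels_at = "all",
                         seed = 1L) {
  stopifnot(n_cells >= 1, all(spacing > 0), length(volume_shape) == 3,
            cell_radius[1] > 0, deformation_amplitude >= 0,
            deformation_coherence_length > 0, n_volumes >= 1,
            reversion_rate >= 0, reversion_rate < 1,
            photobleach_rate >= 0, photobleach_rate < 1)
  structure(as.list(environment()), class = "scene_params")
}

# Smooth random displacement field evaluated at cell positions (micrometres).
# White vector noise on a coarse grid, Gaussian-filtered at the coherence
# length, mean-removed over cells, rescaled to the target median magnitude.
smooth_displacement <- function(pos, params) {
  if (params$deformation_amplitude == 0) return(matrix(0, nrow(pos), 3))
  g <- 4 # coarse grid step, voxels
  shp <- params$volume_shape
  sp <- params$spacing
  gd <- pmax(ceiling(shp / g) + 2L, 3L)
  sig <- params$deformation_coherence_length / (sp * g)
  disp <- matrix(0, nrow(pos), 3)
  # fractional coarse-grid coordinates of the cells
  gc <- sweep(pos, 2, sp * g, "/") + 1
  for (ax in 1:3) {
    f <- array(stats::rnorm(prod(gd)), gd)
    f <- gaussian_blur_3d(f, sig)
    disp[, ax] <- trilinear_at(f, gc)
  }
  disp <- sweep(disp, 2, colMeans(disp))
  mag <- sqrt(rowSums(disp^2))
  med <- stats::median(mag)
  if (med > 0) disp <- disp * (params$deformation_amplitude / med)
  disp
}

# Trilinear interpolation of array `a` (dim nz,ny,nx) at fractional
# 1-based coordinates `q` (n x 3, (z,y,x)).
trilinear_at <- function(a, q) {
  d <- dim(a)
  q[, 1] <- pmin(pmax(q[, 1], 1), d[1])
  q[, 2] <- pmin(pmax(q[, 2], 1), d[2])
  q[, 3] <- pmin(pmax(q[, 3], 1), d[3])
  f <- floor(q)
  f[, 1] <- pmin(f[, 1], d[1] - 1)
  f[, 2] <- pmin(f[, 2], d[2] - 1)
  f[, 3] <- pmin(f[, 3], d[3] - 1)
  w <- q - f
  out <- numeric(nrow(q))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    wt <- (dz * w[, 1] + (1 - dz) * (1 - w[, 1])) *
      (dy * w[, 2] + (1 - dy) * (1 - w[, 2])) *
      (dx * w[, 3] + (1 - dx) * (1 - w[, 3]))
    idx <- cbind(f[, 1] + dz, f[, 2] + dy, f[, 3] + dx)
    out <- out + wt * a[idx]
  }
  out
}

#' Render a synthetic scene with ground truth
#'
#' @param params a [scene_params()] object.
#' @return A `synthetic_scene` list: `movie` (channel 1 nuclear, channel 2
#'   activity when enabled; integer photon counts), `truth_labels` (list of
#'   [label_volume()] per kept time), `truth_tracks` (tibble
#'   `cell_id,t,z_um,y_um,x_um`), `truth_activity` (tibble
#'   `cell_id,t,activity`), `radii_um`, and `params`.
#' @export
render_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(params$seed, {
    shp <- params$volume_shape
    sp <- params$spacing
    extent <- (shp - 1) * sp
    radii <- pmax(stats::rnorm(params$n_cells, params$cell_radius[1],
                               params$cell_radius[2]), 0.5 * params$cell_radius[1])
    margin <- radii[1] * 2 + 1
    lo <- pmin(c(margin, margin, margin), extent / 3)
    hi <- extent - lo
    # non-overlapping initial placement
    pos <- matrix(NA_real_, params$n_cells, 3)
    placed <- 0L
    tries <- 0L
    max_tries <- 5000L * params$n_cells
    while (placed < params$n_cells) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("could not place cells without overlap; reduce n_cells or radius",
             call. = FALSE)
      }
      cand <- lo + stats::runif(3) * (hi - lo)
      if (placed > 0) {
        d <- sqrt(colSums((t(pos[seq_len(placed), , drop = FALSE]) - cand)^2))
        req <- radii[seq_len(placed)] + radii[placed + 1L]
        if (any(d < 1.15 * req)) next
      }
      placed <- placed + 1L
      pos[placed, ] <- cand
    }
    # per-cell rendering amplitude and activity time course
    amp <- stats::runif(params$n_cells, 0.7, 1.3)
    period <- stats::runif(params$n_cells, 10, 30)
    phase <- stats::runif(params$n_cells, 0, 2 * pi)
    activity_of <- function(t) 0.6 + 0.5 * sin(2 * pi * t / period + phase)

    tracks <- vector("list", params$n_volumes)
    frames <- vector("list", params$n_volumes)
    labels <- vector("list", params$n_volumes)
    keep_lab <- if (identical(params$truth_labels_at, "all")) {
      seq_len(params$n_volumes)
    } else as.integer(params$truth_labels_at)
    cur <- pos
    for (t in seq_len(params$n_volumes)) {
      if (t > 1) {
        disp <- smooth_displacement(cur, params)
        # taper each displacement component smoothly to zero toward the
        # wall it points at, so cells never bounce off the volume borders
        # (wall collisions would inject incoherent jumps that no deforming
        # tissue exhibits); tangential motion along a wall stays free
        taper_len <- pmin(8, (hi - lo) / 3)
        wall <- pmin(sweep(cur, 2, lo, "-"), sweep(-cur, 2, hi, "+"))
        w <- pmin(pmax(sweep(wall, 2, taper_len, "/"), 0), 1)
        w <- w * w * (3 - 2 * w) # smoothstep
        cur <- cur + disp * w + params$reversion_rate * (pos - cur)
        for (ax in 1:3) cur[, ax] <- pmin(pmax(cur[, ax], lo[ax]), hi[ax])
        for (pass in 1:3) {
          d2 <- cross_dist2(cur, cur)
          diag(d2) <- Inf
          req <- outer(radii, radii, "+")
          bad <- which(d2 < req^2, arr.ind = TRUE)
          bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
          if (nrow(bad) == 0) break
          for (r in seq_len(nrow(bad))) {
            i <- bad[r, 1]; j <- bad[r, 2]
            v <- cur[j, ] - cur[i, ]
            dn <- sqrt(sum(v^2))
            if (dn < 1e-6) v <- c(0, 0, 1) else v <- v / dn
            push <- (radii[i] + radii[j] - dn) / 2 + 0.05
            cur[i, ] <- pmin(pmax(cur[i, ] - push * v, lo), hi)
            cur[j, ] <- pmin(pmax(cur[j, ] + push * v, lo), hi)
          }
        }
      }
      tracks[[t]] <- tibble::tibble(cell_id = seq_len(params$n_cells), t = t,
                                    z_um = cur[, 1], y_um = cur[, 2], x_um = cur[, 3])
      bleach <- (1 - params$photobleach_rate)^(t - 1)
      nuc <- render_blobs(cur, radii, amp * params$intensity_cell * bleach, shp, sp)
      nuc_counts <- array(stats::rpois(length(nuc),
                                       pmax(nuc + params$intensity_bg, 0)), dim = shp)
      chans <- list(nuc_counts)
      if (params$activity_channel) {
        act_amp <- activity_of(t) * params$intensity_cell * bleach
        act <- render_blobs(cur, radii, act_amp * amp, shp, sp)
        chans[[2]] <- array(stats::rpois(length(act),
                                         pmax(act + params$intensity_bg, 0)), dim = shp)
      }
      frames[[t]] <- chans
      if (t %in% keep_lab) {
        labels[[t]] <- rasterize_labels(cur, radii, shp, sp)
      }
    }
    act_tbl <- tidyr::expand_grid(cell_id = seq_len(params$n_cells),
                                  t = seq_len(params$n_volumes))
    act_tbl$activity <- 0.6 + 0.5 * sin(2 * pi * act_tbl$t / period[act_tbl$cell_id] +
                                          phase[act_tbl$cell_id])
    structure(list(movie = movie(frames, sp),
                   truth_labels = labels,
                   truth_tracks = dplyr::bind_rows(tracks),
                   truth_activity = act_tbl,
                   radii_um = radii,
                   params = params),
              class = "synthetic_scene")
  })
}

# Sum of flat-topped nuclear blobs on local bounding boxes: a
# marker-filled nucleus is roughly uniform inside and falls off sharply
# at its boundary, so the radial profile is a super-Gaussian
# exp(-log(2) (d/r)^4), putting the half-maximum exactly at the nominal
# radius (the FWHM convention for defining a nucleus boundary): ~96% of
# peak at half radius, 50% at the radius, ~1% beyond 1.6 r.
render_blobs <- function(pos, radii, amps, shp, sp) {
  vol <- array(0, shp)
  for (i in seq_len(nrow(pos))) {
    r <- radii[i]
    cvox <- pos[i, ] / sp + 1
    r3 <- ceiling(1.6 * r / sp)
    zr <- max(1, floor(cvox[1] - r3[1])):min(shp[1], ceiling(cvox[1] + r3[1]))
    yr <- max(1, floor(cvox[2] - r3[2])):min(shp[2], ceiling(cvox[2] + r3[2]))
    xr <- max(1, floor(cvox[3] - r3[3])):min(shp[3], ceiling(cvox[3] + r3[3]))
    dz <- ((zr - cvox[1]) * sp[1])^2
    dy <- ((yr - cvox[2]) * sp[2])^2
    dx <- ((xr - cvox[3]) * sp[3])^2
    nd2 <- outer(outer(dz, dy, "+"), dx, "+") / r^2
    g <- exp(-log(2) * nd2 * nd2)
    vol[zr, yr, xr] <- vol[zr, yr, xr] + amps[i] * g
  }
  vol
}

# Ground-truth instance labels: ellipsoidal neighbourhoods, overlaps
# resolved in favour of the nearer centre (normalized distance).
rasterize_labels <- function(pos, radii, shp, sp) {
  lab <- array(0L, shp)
  best <- array(Inf, shp)
  for (i in seq_len(nrow(pos))) {
    r <- radii[i]
    cvox <- pos[i, ] / sp + 1
    rv <- ceiling(r / sp)
    zr <- max(1, floor(cvox[1] - rv[1])):min(shp[1], ceiling(cvox[1] + rv[1]))
    yr <- max(1, floor(cvox[2] - rv[2])):min(shp[2], ceiling(cvox[2] + rv[2]))
    xr <- max(1, floor(cvox[3] - rv[3])):min(shp[3], ceiling(cvox[3] + rv[3]))
    dz <- ((zr - cvox[1]) * sp[1])^2
    dy <- ((yr - cvox[2]) * sp[2])^2
    dx <- ((xr - cvox[3]) * sp[3])^2
    nd <- outer(outer(dz, dy, "+"), dx, "+") / r^2
    sel <- nd <= 1 & nd < best[zr, yr, xr]
    sub_lab <- lab[zr, yr, xr]
    sub_best <- best[zr, yr, xr]
    sub_lab[sel] <- i
    sub_best[sel] <- nd[sel]
    lab[zr, yr, xr] <- sub_lab
    best[zr, yr, xr] <- sub_best
  }
  label_volume(lab, sp)
}

#' Degrade a movie
#'
#' Produces the stress-test variants used to probe robustness: added
#' Poisson noise of a given standard deviation, temporal subsampling
#' (larger per-step movements), and z sum-binning (coarser axial
#' resolution).
#'
#' @param m a [movie()].
#' @param mode one of `"poisson_noise"`, `"temporal_subsample"`, `"z_bin"`.
#' @param sd target noise standard deviation (counts), for
#'   `poisson_noise`: zero-mean-adjusted `Poisson(sd^2) - sd^2` noise is
#'   added per voxel and the result clipped at 0.
#' @param k keep every k-th volume (starting at the first), for
#'   `temporal_subsample`.
#' @param factor number of adjacent z planes to sum, for `z_bin`
#'   (z spacing is multiplied accordingly; trailing planes that do not
#'   fill a group are dropped with a warning).
#' @param seed RNG seed for the noise mode.
#' @return A degraded [movie()].
#' @export
degrade <- function(m, mode = c("poisson_noise", "temporal_subsample", "z_bin"),
                    sd = NULL, k = NULL, factor = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "movie"))
  if (m$n_time < 1) stop("empty movie", call. = FALSE)
  if (mode == "poisson_noise") {
    stopifnot(!is.null(sd), sd > 0)
    lam <- sd^2
    with_seed(seed, {
      frames <- lapply(m$frames, function(chs) {
        lapply(chs, function(v) {
          noise <- stats::rpois(length(v), lam) - lam
          out <- pmax(as.numeric(v) + noise, 0)
          array(out, dim(v))
        })
      })
      movie(frames, m$spacing)
    })
  } else if (mode == "temporal_subsample") {
    stopifnot(!is.null(k), k >= 1, k == round(k))
    movie(m$frames[seq(1, m$n_time, by = k)], m$spacing)
  } else {
    stopifnot(!is.null(factor), factor >= 2, factor == round(factor))
    nz <- m$shape[1]
    ng <- nz %/% factor
    if (ng < 1) stop("too few z planes for the requested binning", call. = FALSE)
    if (ng * factor < nz) {
      warning(sprintf("dropping %d trailing z plane(s) not filling a bin group",
                      nz - ng * factor))
    }
    frames <- lapply(m$frames, function(chs) {
      lapply(chs, function(v) {
        out <- array(0, c(ng, m$shape[2], m$shape[3]))
        for (g in seq_len(ng)) {
          zi <- ((g - 1) * factor + 1):(g * factor)
          out[g, , ] <- apply(v[zi, , , drop = FALSE], c(2, 3), sum)
        }
        out
      })
    })
    spacing <- m$spacing
    spacing[1] <- spacing[1] * factor
    movie(frames, spacing)
  }
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d cells, %d volumes; ", x$params$n_cells,
              x$params$n_volumes))
  print(x$movie)
  invisible(x)
}
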