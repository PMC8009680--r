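#' Train a voxel classifier on one annotated volume
#'
#' Produces per-voxel cell probabilities with one of two pluggable
#' backends, trained on a single annotated volume (the usual situation:
#' one manually corrected volume per recording):
#'
#' * `classical_threshold`: a calibrated intensity threshold with a
#'   logistic soft transition; the threshold is chosen to maximise the
#'   voxelwise F1 score against the binarized annotation.
#' * `unet3d_small`: a reduced 3D encoder-decoder (two pooling levels,
#'   pooling restricted to x-y as the axial resolution is coarser),
#'   trained on randomly cropped patches with x-y-restricted random
#'   affine augmentation and binary cross-entropy loss.
#'
#' Classifiers are intended to run on locally contrast-normalized
#' volumes (see [local_contrast_normalize()]).
#'
#' @param vol annotated [image_volume()] (normalized intensities).
#' @param labels matching [label_volume()] (any positive label = cell).
#' @param backend `"classical_threshold"` or `"unet3d_small"`.
#' @param patch_shape tile/patch extents `(z, y, x)` in voxels; y and x
#'   must be divisible by 4 for the U-Net backend.
#' @param epochs,augment,patches_per_epoch U-Net training settings.
#' @param seed RNG seed for patch sampling and initialization.
#' @param verbose log per-epoch losses.
#' @return A `voxel_classifier` object.
#' @export
train_classifier <- function(vol, labels,
                             backend = c("classical_threshold", "unet3d_small"),
                             patch_shape = c(8, 32, 32),
                             epochs = 20, augment = TRUE,
                             patches_per_epoch = 8,
                             seed = NULL, verbose = FALSE) {
  backend <- match.arg(backend)
  stopifnot(identical(dim(vol), dim(labels)))
  v <- as.numeric(vol)
  fg <- as.numeric(labels) > 0
  if (!any(fg)) stop("annotation contains no cell voxels", call. = FALSE)
  if (backend == "classical_threshold") {
    qs <- stats::quantile(v, seq(0.5, 0.999, by = 0.005), names = FALSE)
    qs <- unique(qs)
    f1 <- vapply(qs, function(th) {
      p <- v > th
      tp <- sum(p & fg)
      if (tp == 0) return(0)
      2 * tp / (sum(p) + sum(fg))
    }, numeric(1))
    th_f1 <- qs[which.max(f1)]
    # guard: never let the boundary hug the background class; the
    # midpoint of the class medians keeps a margin so that noisier
    # recordings than the training volume do not flood the mask
    th_mid <- 0.5 * (stats::median(v[!fg]) + stats::median(v[fg]))
    th <- max(th_f1, th_mid)
    scale <- max(0.05 * (stats::quantile(v, .99, names = FALSE) -
                           stats::quantile(v, .5, names = FALSE)), 1e-6)
    f1_at <- function(th) {
      p <- v > th
      tp <- sum(p & fg)
      if (tp == 0) 0 else 2 * tp / (sum(p) + sum(fg))
    }
    state <- list(threshold = th, scale = scale, f1 = f1_at(th))
  } else {
    d <- dim(vol)
    if (any(d < patch_shape)) {
      stop("annotated volume is smaller than patch_shape", call. = FALSE)
    }
    fit <- train_unet3d(array(v, d), array(as.integer(fg), d),
                        patch_shape = patch_shape, epochs = epochs,
                        augment = augment, patches_per_epoch = patches_per_epoch,
                        seed = seed, verbose = verbose)
    state <- fit
  }
  structure(list(backend = backend, patch_shape = as.integer(patch_shape),
                 state = state),
            class = "voxel_classifier")
}

#' @export
print.voxel_classifier <- function(x, ...) {
  cat(sprintf("<voxel_classifier> backend = %s, patch (z,y,x) = %s\n",
              x$backend, paste(x$patch_shape, collapse = "x")))
  invisible(x)
}

# Predict a single patch-sized block (numeric array), any backend.
predict_patch <- function(clf, block) {
  if (clf$backend == "classical_threshold") {
    array(stats::plogis((block - clf$state$threshold) / clf$state$scale),
          dim(block))
  } else {
    array(unet_forward(clf$state$weights, as.numeric(block), dim(block))$prob,
          dim(block))
  }
}

#' Per-voxel cell probability for a whole volume
#'
#' Tiles the volume into patch-shaped sub-images with 25% overlap,
#' classifies each, and stitches the interior crops (each voxel is taken
#' from the tile whose centre is nearest). Borders smaller than a patch
#' are reflect-padded.
#'
#' @param clf a `voxel_classifier` from [train_classifier()].
#' @param vol an [image_volume()] (normalized intensities).
#' @return An [image_volume()] of probabilities in `[0, 1]`.
#' @export
predict_probability <- function(clf, vol) {
  d <- dim(vol)
  sp <- attr(vol, "spacing")
  if (is.null(sp)) sp <- c(1, 1, 1)
  p <- pmin(clf$patch_shape, d)
  if (clf$backend == "unet3d_small") {
    p[2:3] <- pmax((p[2:3] %/% 4) * 4, 4) # keep poolable
  }
  starts <- lapply(1:3, function(ax) {
    if (d[ax] <= p[ax]) return(1L)
    step <- max(1L, p[ax] - as.integer(round(0.25 * p[ax])))
    s <- seq(1L, d[ax] - p[ax] + 1L, by = step)
    if (s[length(s)] != d[ax] - p[ax] + 1L) s <- c(s, d[ax] - p[ax] + 1L)
    as.integer(s)
  })
  # responsibility cut points per axis: midpoints between tile centres
  resp <- lapply(1:3, function(ax) {
    s <- starts[[ax]]
    k <- length(s)
    lo <- integer(k); hi <- integer(k)
    for (i in seq_len(k)) {
      lo[i] <- if (i == 1) 1L else as.integer(floor((s[i - 1] + s[i] + p[ax]) / 2))
      hi[i] <- if (i == k) d[ax] else as.integer(floor((s[i] + s[i + 1] + p[ax]) / 2) - 1L)
    }
    list(lo = lo, hi = hi)
  })
  a <- unclass(vol); attributes(a) <- list(dim = d)
  out <- array(NA_real_, d)
  for (iz in seq_along(starts[[1]])) for (iy in seq_along(starts[[2]]))
    for (ix in seq_along(starts[[3]])) {
      s <- c(starts[[1]][iz], starts[[2]][iy], starts[[3]][ix])
      zr <- s[1]:(s[1] + p[1] - 1); yr <- s[2]:(s[2] + p[2] - 1)
      xr <- s[3]:(s[3] + p[3] - 1)
      block <- a[zr, yr, xr, drop = FALSE]
      pr <- predict_patch(clf, array(block, p))
      rz <- resp[[1]]$lo[iz]:resp[[1]]$hi[iz]
      ry <- resp[[2]]$lo[iy]:resp[[2]]$hi[iy]
      rx <- resp[[3]]$lo[ix]:resp[[3]]$hi[ix]
      out[rz, ry, rx] <- pr[rz - s[1] + 1, ry - s[2] + 1, rx - s[3] + 1]
    }
  image_volume(out, sp)
}

#' Instance segmentation by two-stage seeded watershed
#'
#' Voxels with probability strictly greater than 0.5 form the cell-like
#' mask. A Euclidean distance-to-background map (anisotropic, physical
#' units) is computed on the mask and Gaussian-blurred; its local maxima
#' (merged over plateaus, with a minimum separation keyed to
#' `min_cell_size`) become seeds. Seeded watershed is applied twice:
#' first per x-y plane (where the resolution is finest), then in full 3D;
#' each in-plane region is assigned the 3D label that dominates it, with
#' seed-bearing regions pinned to their seed. Labels smaller than
#' `min_cell_size` voxels are removed and the rest renumbered
#' consecutively.
#'
#' @param prob an [image_volume()] of probabilities in `[0, 1]`.
#' @param min_cell_size minimum voxels per retained cell.
#' @param blur_sigma Gaussian blur of the distance map, voxels (default 1).
#' @param prob_threshold mask threshold (fixed at 0.5 in the method;
#'   exposed for completeness).
#' @return A [label_volume()] with attribute `"seeds"` (linear indices of
#'   the accepted peaks).
#' @export
instance_segment <- function(prob, min_cell_size, blur_sigma = 1,
                             prob_threshold = 0.5) {
  stopifnot(min_cell_size >= 1, prob_threshold > 0, prob_threshold < 1)
  d <- dim(prob)
  sp <- attr(prob, "spacing")
  if (is.null(sp)) sp <- c(1, 1, 1)
  pv <- as.numeric(prob)
  if (any(pv < -1e-9 | pv > 1 + 1e-9)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  mask <- as.integer(pv > prob_threshold)
  if (!any(mask == 1L)) {
    warning("empty cell-like mask; returning all-background labels")
    return(label_volume(array(0L, d), sp))
  }
  dist <- cpp_edt3d(mask, d, sp)
  bl <- gaussian_blur_3d(array(dist, d), rep(blur_sigma, 3))
  # minimum seed separation keyed to the only size scale available:
  # the physical edge length of a min_cell_size cube, converted per axis
  sep_um <- (min_cell_size * prod(sp))^(1 / 3)
  sep <- pmax(1L, as.integer(round(sep_um / sp)))
  peaks <- cpp_find_peaks(as.numeric(bl), mask, d, sep)
  if (length(peaks) == 0) {
    warning("no seeds found; returning all-background labels")
    return(label_volume(array(0L, d), sp))
  }
  seeds <- integer(prod(d))
  seeds[peaks] <- seq_along(peaks)
  lab2 <- cpp_watershed(as.numeric(bl), mask, seeds, d, TRUE)
  lab3 <- cpp_watershed(as.numeric(bl), mask, seeds, d, FALSE)
  lab <- lab3
  # majority vote of the 3D labels within each in-plane region
  # (group = (plane, 2D region); sort-based aggregation keeps memory
  # proportional to the mask even when noise spawns many candidates)
  in2d <- which(lab2 > 0L)
  if (length(in2d)) {
    z <- (in2d - 1L) %% d[1]
    nlab <- length(peaks)
    key <- as.numeric(z) * nlab + (lab2[in2d] - 1) # group id
    l3 <- lab3[in2d]
    o <- order(key, l3)
    k_s <- key[o]; l_s <- l3[o]
    n <- length(o)
    new_run <- c(TRUE, k_s[-1] != k_s[-n] | l_s[-1] != l_s[-n])
    starts <- which(new_run)
    counts <- diff(c(starts, n + 1L))
    run_key <- k_s[starts]
    run_lab <- l_s[starts]
    # per group, the label with the highest count wins
    o2 <- order(run_key, -counts)
    first <- !duplicated(run_key[o2])
    best_key <- run_key[o2][first]
    best_lab <- run_lab[o2][first]
    # pin seed-bearing in-plane regions to their seed's label
    pz <- (peaks - 1L) %% d[1]
    pkey <- as.numeric(pz) * nlab + (lab2[peaks] - 1)
    hit <- match(pkey, best_key)
    ok <- !is.na(hit)
    best_lab[hit[ok]] <- seq_along(peaks)[ok]
    lab[in2d] <- best_lab[match(key, best_key)]
  }
  # minimum size filter + consecutive relabeling
  sizes <- tabulate(lab, nbins = length(peaks))
  keep <- which(sizes >= min_cell_size)
  remap <- integer(length(peaks))
  remap[keep] <- seq_along(keep)
  nzi <- which(lab > 0L)
  lab[nzi] <- remap[lab[nzi]]
  out <- label_volume(array(as.integer(lab), d), sp)
  attr(out, "seeds") <- peaks[keep]
  out
}

#' Load the manually corrected first-volume segmentation
#'
#' Reads an integer label TIFF (one page per z plane), validates it, and
#' returns the label volume whose regions define the tracked cell
#' identities for the whole movie.
#'
#' @param path TIFF file path.
#' @param spacing voxel spacing `(z, y, x)` micrometres.
#' @param expected_shape optional `(z, y, x)` shape to validate against.
#' @return A [label_volume()].
#' @export
load_first_volume_segmentation <- function(path, spacing,
                                           expected_shape = NULL) {
  lab <- read_label_tiff(path, spacing)
  if (!is.null(expected_shape) && !identical(dim(lab), as.integer(expected_shape))) {
    stop(sprintf("label volume shape (%s) does not match the movie (%s)",
                 paste(dim(lab), collapse = "x"),
                 paste(expected_shape, collapse = "x")), call. = FALSE)
  }
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (length(ids) == 0) stop("no cells in first volume", call. = FALSE)
  bad <- ids[!vapply(ids, function(l) is_connected_label(lab, l), logical(1))]
  if (length(bad)) {
    warning(sprintf("labels with disconnected components: %s",
                    paste(bad, collapse = ", ")))
  }
  lab
}

# 6-connectivity check of one label's voxel set.
is_connected_label <- function(lab, l) {
  d <- dim(lab)
  idx <- which(lab == l)
  if (length(idx) <= 1) return(TRUE)
  inset <- integer(0)
  member <- new.env(hash = TRUE, size = length(idx))
  for (i in idx) assign(as.character(i), TRUE, envir = member)
  visited <- new.env(hash = TRUE, size = length(idx))
  stack <- idx[1]
  assign(as.character(idx[1]), TRUE, envir = visited)
  nz <- d[1]; ny <- d[2]; nvox <- prod(d)
  count <- 0L
  while (length(stack)) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    count <- count + 1L
    z <- (i - 1L) %% nz
    y <- ((i - 1L) %/% nz) %% ny
    x <- (i - 1L) %/% (nz * ny)
    nbrs <- c(if (z > 0) i - 1L, if (z < nz - 1) i + 1L,
              if (y > 0) i - nz, if (y < ny - 1) i + nz,
              if (x > 0) i - nz * ny, if (x < d[3] - 1) i + nz * ny)
    for (j in nbrs) {
      cj <- as.character(j)
      if (exists(cj, envir = member, inherits = FALSE) &&
          !exists(cj, envir = visited, inherits = FALSE)) {
        assign(cj, TRUE, envir = visited)
        stack <- c(stack, j)
      }
    }
  }
  count == length(idx)
}

#' Cell centres of a label volume
#'
#' Per-label centroid in physical micrometre coordinates (0-based voxel
#' convention), ordered by label id.
#'
#' @param labels a [label_volume()].
#' @param spacing optional override of the voxel spacing `(z, y, x)`.
#' @return A tibble `cell_id, z_um, y_um, x_um`.
#' @export
centers_of <- function(labels, spacing = NULL) {
  if (is.null(spacing)) spacing <- spacing_of(labels)
  d <- dim(labels)
  idx <- which(labels > 0L)
  if (length(idx) == 0) stop("label volume has no labels", call. = FALSE)
  l <- as.integer(labels[idx])
  z <- ((idx - 1L) %% d[1]) * spacing[1]
  y <- (((idx - 1L) %/% d[1]) %% d[2]) * spacing[2]
  x <- ((idx - 1L) %/% (d[1] * d[2])) * spacing[3]
  ids <- sort(unique(l))
  n <- tabulate(l)[ids]
  tibble::tibble(cell_id = ids,
                 z_um = rowsum(z, l)[, 1] / n,
                 y_um = rowsum(y, l)[, 1] / n,
                 x_um = rowsum(x, l)[, 1] / n)
}
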