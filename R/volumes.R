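#' Volumetric image containers
#'
#' A 3D fluorescence volume is stored as a numeric array with dimensions
#' `(z, y, x)` and a physical voxel `spacing` attribute in micrometres,
#' also in `(z, y, x)` order. A label volume is the integer counterpart
#' with 0 meaning background. A movie is a time- and channel-indexed list
#' of volumes sharing one spacing.
#'
#' Physical coordinates use the 0-based voxel convention: the centre of
#' voxel `(i, j, k)` (1-based R index) lies at `(i - 1, j - 1, k - 1) *
#' spacing` micrometres.
#'
#' @param data numeric (or integer for labels) 3D array, dim `(z, y, x)`.
#' @param spacing numeric length-3, micrometres per voxel in `(z, y, x)`.
#' @return An `image_volume` / `label_volume` object (array subclass).
#' @export
image_volume <- function(data, spacing) {
  stopifnot(length(dim(data)) == 3, length(spacing) == 3, all(spacing > 0))
  structure(data, spacing = as.numeric(spacing),
            class = c("image_volume", class(data)))
}

#' @rdname image_volume
#' @export
label_volume <- function(data, spacing) {
  stopifnot(length(dim(data)) == 3, length(spacing) == 3, all(spacing > 0))
  if (!is.integer(data)) {
    storage.mode(data) <- "integer"
  }
  if (any(data < 0L, na.rm = TRUE)) {
    stop("label volumes cannot contain negative labels", call. = FALSE)
  }
  structure(data, spacing = as.numeric(spacing),
            class = c("label_volume", class(unclass(data))))
}

#' @rdname image_volume
#' @param x object to query.
#' @export
spacing_of <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) stop("object carries no voxel spacing", call. = FALSE)
  sp
}

#' Assemble a movie from per-time, per-channel volumes
#'
#' @param frames list over time of lists over channel of 3D arrays
#'   (all the same shape).
#' @param spacing voxel spacing `(z, y, x)` in micrometres.
#' @return A `movie` object.
#' @export
movie <- function(frames, spacing) {
  stopifnot(length(frames) >= 1)
  if (!is.list(frames[[1]])) frames <- lapply(frames, list)
  shp <- dim(frames[[1]][[1]])
  stopifnot(length(shp) == 3)
  for (t in seq_along(frames)) {
    for (ch in seq_along(frames[[t]])) {
      if (!identical(dim(frames[[t]][[ch]]), shp)) {
        stop(sprintf("volume at t=%d, channel=%d has inconsistent shape", t, ch),
             call. = FALSE)
      }
    }
  }
  structure(list(frames = frames, spacing = as.numeric(spacing),
                 shape = shp, n_time = length(frames),
                 n_channel = length(frames[[1]])),
            class = "movie")
}

#' @rdname movie
#' @param m a `movie`.
#' @param t time index (1-based).
#' @param channel channel index (1-based).
#' @export
movie_frame <- function(m, t, channel = 1) {
  stopifnot(inherits(m, "movie"), t >= 1, t <= m$n_time)
  image_volume(m$frames[[t]][[channel]], m$spacing)
}

#' @export
print.movie <- function(x, ...) {
  cat(sprintf("<movie> %d volumes x %d channel(s), shape (z,y,x) = %s, spacing %s um\n",
              x$n_time, x$n_channel,
              paste(x$shape, collapse = "x"),
              paste(signif(x$spacing, 3), collapse = ", ")))
  invisible(x)
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> shape (z,y,x) = %s, spacing %s um, range [%.3g, %.3g]\n",
              paste(dim(x), collapse = "x"),
              paste(signif(spacing_of(x), 3), collapse = ", "),
              min(x), max(x)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> shape (z,y,x) = %s, %d labels\n",
              paste(dim(x), collapse = "x"), length(setdiff(unique(as.vector(x)), 0L))))
  invisible(x)
}

# ---- internal separable filters ------------------------------------------

# Symmetric padding of the rows of a matrix (edge row duplicated).
pad_rows_symmetric <- function(m, h, n) {
  pre <- pmin(pmax(h:1, 1), n)
  post <- pmin(pmax(n:(n - h + 1), 1), n)
  rbind(m[pre, , drop = FALSE], m, m[post, , drop = FALSE])
}

# Apply a 1D symmetric-padded moving filter along one axis of a 3D array
# by shift-and-add over the kernel taps (vectorized across all lines).
filter_axis <- function(a, kern, axis) {
  n <- dim(a)[axis]
  klen <- length(kern)
  if (klen <= 1) return(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  b <- aperm(a, perm)
  db <- dim(b)
  m <- matrix(b, nrow = db[1])
  h <- klen %/% 2
  mp <- pad_rows_symmetric(m, h, n)
  out <- kern[1] * mp[1:n, , drop = FALSE]
  for (j in 2:klen) out <- out + kern[j] * mp[j:(j + n - 1), , drop = FALSE]
  aperm(array(out, dim = db), order(perm))
}

# Moving average along one axis in O(n) per line via column-wise
# cumulative sums (uniform kernel of width k, symmetric padding).
box_mean_axis <- function(a, k, axis) {
  n <- dim(a)[axis]
  if (k <= 1) return(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  b <- aperm(a, perm)
  db <- dim(b)
  m <- matrix(b, nrow = db[1])
  h <- k %/% 2
  mp <- pad_rows_symmetric(m, h, n)
  R <- nrow(mp)
  cs <- matrix(cumsum(as.numeric(mp)), R)
  # cs bleeds across columns of the flattened matrix; the bleed cancels
  # in row differences, and the first row subtracts it explicitly
  bleed <- c(0, cs[R, -ncol(cs)])
  top <- cs[(2 * h + 1):(2 * h + n), , drop = FALSE]
  bottom <- rbind(bleed, cs[seq_len(n - 1), , drop = FALSE])
  aperm(array((top - bottom) / k, dim = db), order(perm))
}

# Box mean over a (kz, ky, kx) window with symmetric border padding.
box_mean_3d <- function(a, k) {
  for (axis in 1:3) {
    if (k[axis] > 1) a <- box_mean_axis(a, k[axis], axis)
  }
  a
}

# Separable Gaussian blur; sigma per axis in voxels (0 skips the axis).
gaussian_blur_3d <- function(a, sigma) {
  for (axis in 1:3) {
    s <- sigma[axis]
    if (s > 0) {
      r <- max(1L, ceiling(3 * s))
      kern <- stats::dnorm(seq(-r, r), sd = s)
      kern <- kern / sum(kern)
      a <- filter_axis(a, kern, axis)
    }
  }
  a
}
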