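# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state; with seed = NULL the current stream is used (and advanced).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Coerce a point set to an n x 3 matrix with columns (z, y, x) in
# micrometres, carrying integer cell ids in attr "ids". Accepts matrices
# and data frames with columns z/y/x or z_um/y_um/x_um (+ optional cell_id).
as_point_matrix <- function(pts) {
  if (is.matrix(pts)) {
    stopifnot(ncol(pts) == 3)
    ids <- attr(pts, "ids")
    if (is.null(ids)) ids <- seq_len(nrow(pts))
    m <- pts
    colnames(m) <- c("z", "y", "x")
    attr(m, "ids") <- as.integer(ids)
    return(m)
  }
  if (is.data.frame(pts)) {
    nm <- names(pts)
    cols <- if (all(c("z_um", "y_um", "x_um") %in% nm)) c("z_um", "y_um", "x_um")
    else if (all(c("z", "y", "x") %in% nm)) c("z", "y", "x")
    else stop("point data frame needs columns z/y/x or z_um/y_um/x_um", call. = FALSE)
    m <- as.matrix(pts[, cols])
    colnames(m) <- c("z", "y", "x")
    ids <- if ("cell_id" %in% nm) as.integer(pts$cell_id) else seq_len(nrow(pts))
    attr(m, "ids") <- ids
    return(m)
  }
  stop("cannot interpret point set", call. = FALSE)
}

point_tibble <- function(m) {
  ids <- attr(m, "ids")
  if (is.null(ids)) ids <- seq_len(nrow(m))
  tibble::tibble(cell_id = as.integer(ids),
                 z_um = m[, 1], y_um = m[, 2], x_um = m[, 3])
}

# Squared Euclidean cross-distances between rows of two matrices.
cross_dist2 <- function(a, b) {
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Distance from each row to its nearest other row.
nn_distance <- function(m) {
  d2 <- cross_dist2(m, m)
  diag(d2) <- Inf
  sqrt(apply(d2, 1, min))
}

# Index of each row's nearest other row (ties: lowest index).
nn_index <- function(m) {
  d2 <- cross_dist2(m, m)
  diag(d2) <- Inf
  apply(d2, 1, which.min)
}
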