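# Independent brute-force oracles, deliberately simple and separate from
# the implementation paths they check.

# Windowed mean/sd at one voxel by direct summation with symmetric padding.
oracle_window_stats <- function(a, center, k) {
  d <- dim(a)
  h <- k %/% 2
  reflect <- function(i, n) {
    i[i < 1] <- 1 - i[i < 1] # symmetric with edge: 0 -> 1, -1 -> 2
    i[i > n] <- 2 * n - i[i > n] + 1
    i
  }
  zi <- reflect((center[1] - h[1]):(center[1] + h[1]), d[1])
  yi <- reflect((center[2] - h[2]):(center[2] + h[2]), d[2])
  xi <- reflect((center[3] - h[3]):(center[3] + h[3]), d[3])
  v <- as.numeric(a[zi, yi, xi])
  c(mean = mean(v), sd = sqrt(mean(v^2) - mean(v)^2))
}

# Greedy matching by explicit repeated scan of the score matrix.
oracle_greedy <- function(m, min_score = 0.5) {
  used_r <- logical(nrow(m)); used_c <- logical(ncol(m))
  out <- NULL
  repeat {
    best <- -Inf; bi <- 0; bj <- 0
    for (i in seq_len(nrow(m))) {
      if (used_r[i]) next
      for (j in seq_len(ncol(m))) {
        if (used_c[j]) next
        if (m[i, j] > best) { best <- m[i, j]; bi <- i; bj <- j }
      }
    }
    if (!is.finite(best) || best < min_score) break
    out <- rbind(out, c(bi, bj, best))
    used_r[bi] <- TRUE; used_c[bj] <- TRUE
    if (all(used_r) || all(used_c)) break
  }
  out
}

# Per-cell-and-step relative movement by direct O(n^2) computation.
oracle_rm <- function(tracks) {
  ts <- sort(unique(tracks$t))
  rows <- NULL
  for (k in 2:length(ts)) {
    cur <- tracks[tracks$t == ts[k], ]; cur <- cur[order(cur$cell_id), ]
    prv <- tracks[tracks$t == ts[k - 1], ]; prv <- prv[order(prv$cell_id), ]
    for (i in seq_len(nrow(cur))) {
      p <- c(cur$z_um[i], cur$y_um[i], cur$x_um[i])
      q <- c(prv$z_um[i], prv$y_um[i], prv$x_um[i])
      mv <- sqrt(sum((p - q)^2))
      nn <- Inf
      for (j in seq_len(nrow(cur))) {
        if (j == i) next
        pj <- c(cur$z_um[j], cur$y_um[j], cur$x_um[j])
        nn <- min(nn, sqrt(sum((p - pj)^2)))
      }
      rows <- rbind(rows, data.frame(cell_id = cur$cell_id[i], t = ts[k],
                                     rm = mv / nn))
    }
  }
  rows
}

# Per-label centroid by explicit per-voxel accumulation.
oracle_centroids <- function(lab, spacing) {
  d <- dim(lab)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  out <- NULL
  for (l in ids) {
    sz <- 0; acc <- c(0, 0, 0)
    for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
      if (lab[z, y, x] == l) {
        sz <- sz + 1
        acc <- acc + (c(z, y, x) - 1) * spacing
      }
    }
    out <- rbind(out, c(l, acc / sz))
  }
  out
}

# Kernel-regularized least squares fit of matched displacements
# (the closed form the EM registration must reduce to in the noiseless,
# fully matched, zero-outlier case).
oracle_kernel_fit <- function(A, B_matched, beta, lam, sigma2) {
  G <- exp(-as.matrix(dist(A))^2 / (2 * beta^2))
  solve(G + lam * sigma2 * diag(nrow(A)), B_matched - A)
}
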