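#' Neighborhood descriptor of a point
#'
#' Each cell centre is described by the positions of its 20 nearest
#' neighbours: the offsets (neighbour minus point, physical coordinates)
#' are divided by the mean neighbour distance, the 20 normalized offset
#' triples are sorted by ascending magnitude (ties broken by z, y, x
#' lexicographic order of the offset), and the mean distance itself is
#' appended, giving a 61-component vector. Components 1-60 are invariant
#' to translation and to uniform scaling of the point set; component 61
#' carries the absolute scale.
#'
#' @param i point index.
#' @param pts point set: matrix or data frame (>= 21 points; see
#'   [generate_training_pairs()] for accepted forms).
#' @return Numeric vector of length 61.
#' @export
build_feature <- function(i, pts) {
  m <- as_point_matrix(pts)
  if (nrow(m) < 21) {
    stop("building the neighborhood descriptor requires at least 21 points",
         call. = FALSE)
  }
  stopifnot(i >= 1, i <= nrow(m))
  build_features_all(m)[i, ]
}

# Descriptors for every point of a set (n x 61 matrix).
build_features_all <- function(m) {
  n <- nrow(m)
  if (n < 21) stop("requires at least 21 points", call. = FALSE)
  d2 <- cross_dist2(m, m)
  diag(d2) <- Inf
  out <- matrix(NA_real_, n, 61)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[1:20]
    off <- m[nb, , drop = FALSE] - matrix(m[i, ], 20, 3, byrow = TRUE)
    dbar <- mean(sqrt(rowSums(off^2)))
    offn <- off / dbar
    mag <- sqrt(rowSums(offn^2))
    o <- order(mag, offn[, 1], offn[, 2], offn[, 3])
    out[i, ] <- c(t(offn[o, , drop = FALSE]), dbar)
  }
  out
}

# ---- network internals ----------------------------------------------------

ffn_init <- function(hidden = 512L, seed = NULL) {
  with_seed(seed, {
    h <- as.integer(hidden)
    init <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nc)), nr, nc)
    structure(list(
      W1 = init(h, 61), b1 = numeric(h),
      bn1 = list(gamma = rep(1, h), beta = numeric(h),
                 mean = numeric(h), var = rep(1, h)),
      W2 = init(h, 2 * h), b2 = numeric(h),
      bn2 = list(gamma = rep(1, h), beta = numeric(h),
                 mean = numeric(h), var = rep(1, h)),
      W3 = matrix(stats::rnorm(h, 0, sqrt(1 / h)), 1, h), b3 = 0,
      hidden = h,
      history = NULL
    ), class = "ffn_fit")
  })
}

bn_fwd_train <- function(x, bn, eps = 1e-5) {
  mu <- colMeans(x)
  v <- colMeans(sweep(x, 2, mu)^2)
  xhat <- sweep(sweep(x, 2, mu), 2, sqrt(v + eps), "/")
  y <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
  list(y = y, xhat = xhat, mu = mu, var = v, eps = eps)
}

bn_fwd_infer <- function(x, bn, eps = 1e-5) {
  s <- bn$gamma / sqrt(bn$var + eps)
  sweep(sweep(x, 2, s, "*"), 2, bn$beta - bn$mean * s, "+")
}

bn_bwd <- function(dy, cache, bn) {
  n <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  inv_sd <- 1 / sqrt(cache$var + cache$eps)
  t1 <- sweep(dy, 2, dbeta / n)
  t2 <- sweep(cache$xhat, 2, colSums(dy * cache$xhat) / n, "*")
  dx <- sweep(t1 - t2, 2, bn$gamma * inv_sd, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Training-mode forward through the full pair network. fa, fb: n x 61.
ffn_fwd_train <- function(net, fa, fb) {
  n <- nrow(fa)
  z1 <- rbind(fa, fb) %*% t(net$W1) # 2n x h (shared encoder)
  z1 <- sweep(z1, 2, net$b1, "+")
  bn1 <- bn_fwd_train(z1, net$bn1)
  h1 <- pmax(bn1$y, 0)
  cat12 <- cbind(h1[seq_len(n), , drop = FALSE], h1[n + seq_len(n), , drop = FALSE])
  z2 <- sweep(cat12 %*% t(net$W2), 2, net$b2, "+")
  bn2 <- bn_fwd_train(z2, net$bn2)
  h2 <- pmax(bn2$y, 0)
  logit <- as.numeric(h2 %*% t(net$W3)) + net$b3
  p <- stats::plogis(logit)
  list(p = p, cache = list(z1 = z1, bn1 = bn1, h1 = h1, cat12 = cat12,
                           z2 = z2, bn2 = bn2, h2 = h2, n = n))
}

ffn_bwd <- function(net, fw, fa, fb, label) {
  K <- fw$cache
  n <- K$n
  h <- net$hidden
  dlogit <- (fw$p - label) / n
  dW3 <- matrix(colSums(K$h2 * dlogit), 1, h)
  db3 <- sum(dlogit)
  dh2 <- outer(dlogit, as.numeric(net$W3))
  dz2bn <- dh2 * (K$bn2$y > 0)
  b2g <- bn_bwd(dz2bn, K$bn2, net$bn2)
  dW2 <- crossprod(b2g$dx, K$cat12)
  db2 <- colSums(b2g$dx)
  dcat <- b2g$dx %*% net$W2
  dh1 <- rbind(dcat[, seq_len(h), drop = FALSE],
               dcat[, h + seq_len(h), drop = FALSE])
  dz1bn <- dh1 * (K$bn1$y > 0)
  b1g <- bn_bwd(dz1bn, K$bn1, net$bn1)
  dW1 <- crossprod(b1g$dx, rbind(fa, fb))
  db1 <- colSums(b1g$dx)
  list(W1 = dW1, b1 = db1, bn1g = b1g$dgamma, bn1b = b1g$dbeta,
       W2 = dW2, b2 = db2, bn2g = b2g$dgamma, bn2b = b2g$dbeta,
       W3 = dW3, b3 = db3)
}

#' Train the point-matching network
#'
#' Fits the three-layer similarity network (61 -> 512 shared per-point
#' encoder, 1024 -> 512 comparison layer, -> 1 sigmoid; batch
#' normalization before each ReLU) on labeled feature pairs by Adam on
#' the binary cross-entropy, with batch-normalization statistics frozen
#' into running averages for inference.
#'
#' @param pairs tibble from [generate_training_pairs()] (columns `label`,
#'   `feature_a`, `feature_b`).
#' @param epochs passes over the training pairs (default 10).
#' @param batch_size minibatch size (default 128).
#' @param lr Adam learning rate.
#' @param holdout_fraction fraction of pairs held out to report validation
#'   accuracy (default 0.1).
#' @param hidden hidden-layer width (default 512).
#' @param seed RNG seed (initialization and shuffling).
#' @param verbose print per-epoch loss and held-out accuracy.
#' @return An `ffn_fit` object with a `history` tibble.
#' @export
train_ffn <- function(pairs, epochs = 10, batch_size = 128, lr = 1e-3,
                      holdout_fraction = 0.1, hidden = 512L, seed = NULL,
                      verbose = FALSE) {
  stopifnot(all(c("label", "feature_a", "feature_b") %in% names(pairs)))
  lab <- as.numeric(pairs$label)
  if (length(unique(lab)) < 2) {
    stop("training stream contains a single class", call. = FALSE)
  }
  fa <- pairs$feature_a
  fb <- pairs$feature_b
  with_seed(seed, {
    net <- ffn_init(hidden)
    n <- length(lab)
    n_hold <- floor(holdout_fraction * n)
    perm <- sample.int(n)
    hold <- perm[seq_len(n_hold)]
    trn <- if (n_hold > 0) perm[-seq_len(n_hold)] else perm
    adam <- list(t = 0, m = list(), v = list())
    param_names <- c("W1", "b1", "W2", "b2", "W3", "b3")
    bn_names <- c("bn1g", "bn1b", "bn2g", "bn2b")
    mom <- 0.1
    hist <- vector("list", epochs)
    for (ep in seq_len(epochs)) {
      idx <- sample(trn)
      tot <- 0; nb <- 0
      for (s in seq(1, length(idx), by = batch_size)) {
        b <- idx[s:min(s + batch_size - 1, length(idx))]
        if (length(b) < 2) next
        fw <- ffn_fwd_train(net, fa[b, , drop = FALSE], fb[b, , drop = FALSE])
        pr <- pmin(pmax(fw$p, 1e-7), 1 - 1e-7)
        tot <- tot + mean(-lab[b] * log(pr) - (1 - lab[b]) * log(1 - pr))
        nb <- nb + 1
        # update running BN statistics
        net$bn1$mean <- (1 - mom) * net$bn1$mean + mom * fw$cache$bn1$mu
        net$bn1$var <- (1 - mom) * net$bn1$var + mom * fw$cache$bn1$var
        net$bn2$mean <- (1 - mom) * net$bn2$mean + mom * fw$cache$bn2$mu
        net$bn2$var <- (1 - mom) * net$bn2$var + mom * fw$cache$bn2$var
        g <- ffn_bwd(net, fw, fa[b, , drop = FALSE], fb[b, , drop = FALSE], lab[b])
        adam$t <- adam$t + 1
        upd <- function(key, gval) {
          if (is.null(adam$m[[key]])) {
            adam$m[[key]] <<- gval * 0
            adam$v[[key]] <<- gval * 0
          }
          adam$m[[key]] <<- 0.9 * adam$m[[key]] + 0.1 * gval
          adam$v[[key]] <<- 0.999 * adam$v[[key]] + 0.001 * gval * gval
          mh <- adam$m[[key]] / (1 - 0.9^adam$t)
          vh <- adam$v[[key]] / (1 - 0.999^adam$t)
          lr * mh / (sqrt(vh) + 1e-8)
        }
        for (pn in param_names) net[[pn]] <- net[[pn]] - upd(pn, g[[pn]])
        net$bn1$gamma <- net$bn1$gamma - upd("bn1g", g$bn1g)
        net$bn1$beta <- net$bn1$beta - upd("bn1b", g$bn1b)
        net$bn2$gamma <- net$bn2$gamma - upd("bn2g", g$bn2g)
        net$bn2$beta <- net$bn2$beta - upd("bn2b", g$bn2b)
      }
      val_acc <- NA_real_
      if (n_hold > 0) {
        ph <- ffn_score_features(net, fa[hold, , drop = FALSE],
                                 fb[hold, , drop = FALSE])
        val_acc <- mean((ph > 0.5) == (lab[hold] == 1))
      }
      hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = tot / max(nb, 1),
                                   val_accuracy = val_acc)
      if (verbose) {
        message(sprintf("epoch %d: BCE %.4f, held-out accuracy %s", ep,
                        tot / max(nb, 1),
                        ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
      }
    }
    net$history <- dplyr::bind_rows(hist)
    net
  })
}

# Inference scores for matched rows of fa/fb (frozen BN statistics).
ffn_score_features <- function(net, fa, fb) {
  h1 <- pmax(bn_fwd_infer(sweep(rbind(fa, fb) %*% t(net$W1), 2, net$b1, "+"),
                          net$bn1), 0)
  n <- nrow(fa)
  cat12 <- cbind(h1[seq_len(n), , drop = FALSE], h1[n + seq_len(n), , drop = FALSE])
  h2 <- pmax(bn_fwd_infer(sweep(cat12 %*% t(net$W2), 2, net$b2, "+"), net$bn2), 0)
  stats::plogis(as.numeric(h2 %*% t(net$W3)) + net$b3)
}

#' @export
print.ffn_fit <- function(x, ...) {
  cat(sprintf("<ffn_fit> 61 -> %d -> %d -> 1 pair-similarity network\n",
              x$hidden, x$hidden))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs; final BCE %.4f, held-out accuracy %s\n",
                nrow(x$history), last$train_loss,
                ifelse(is.na(last$val_accuracy), "-",
                       sprintf("%.3f", last$val_accuracy))))
  }
  invisible(x)
}

#' Score all cross-volume point pairs
#'
#' Computes the similarity matrix between every point of `setA` and every
#' point of `setB` under a trained network. The comparison layer is
#' additive in the two encodings, so the full matrix is computed from two
#' per-set projections plus an outer sum -- identical to scoring each
#' pair through the network, without materialising all pairs.
#'
#' @param net an `ffn_fit`.
#' @param setA,setB point sets (>= 21 points each).
#' @return `|setA| x |setB|` matrix of scores in `(0, 1)`.
#' @export
score_pairs <- function(net, setA, setB) {
  ma <- as_point_matrix(setA)
  mb <- as_point_matrix(setB)
  fa <- build_features_all(ma)
  fb <- build_features_all(mb)
  score_feature_sets(net, fa, fb)
}

score_feature_sets <- function(net, fa, fb) {
  h <- net$hidden
  enc <- pmax(bn_fwd_infer(sweep(rbind(fa, fb) %*% t(net$W1), 2, net$b1, "+"),
                           net$bn1), 0)
  ha <- enc[seq_len(nrow(fa)), , drop = FALSE]
  hb <- enc[nrow(fa) + seq_len(nrow(fb)), , drop = FALSE]
  W2a <- net$W2[, seq_len(h), drop = FALSE]
  W2b <- net$W2[, h + seq_len(h), drop = FALSE]
  s <- net$bn2$gamma / sqrt(net$bn2$var + 1e-5)
  const <- (net$b2 - net$bn2$mean) * s + net$bn2$beta
  Ps <- sweep(ha %*% t(W2a), 2, s, "*")
  Qs <- sweep(hb %*% t(W2b), 2, s, "*")
  nA <- nrow(fa); nB <- nrow(fb)
  out <- matrix(NA_real_, nA, nB)
  w3 <- as.numeric(net$W3)
  chunk <- max(1L, as.integer(2e6 / max(nA, 1)))
  for (s0 in seq(1, nB, by = chunk)) {
    js <- s0:min(s0 + chunk - 1, nB)
    for (j in js) {
      pre <- sweep(Ps, 2, Qs[j, ] + const, "+")
      out[, j] <- stats::plogis(pmax(pre, 0) %*% w3 + net$b3)
    }
  }
  out
}

#' Greedy one-to-one initial matching
#'
#' Repeatedly selects the globally highest remaining score, records the
#' pair, and removes its row and column; stops when the best remaining
#' score falls below `min_score` or one side is exhausted. Ties are
#' resolved toward the lowest row index, then the lowest column index,
#' so the result is deterministic.
#'
#' @param scores similarity matrix (rows: set A, columns: set B).
#' @param min_score minimum score for an accepted pair (default 0.5).
#' @return Tibble `a, b, score`, with attributes `unmatched_a` and
#'   `unmatched_b` (indices left unpaired).
#' @export
greedy_match <- function(scores, min_score = 0.5) {
  stopifnot(is.matrix(scores))
  m <- scores
  nA <- nrow(m); nB <- ncol(m)
  a <- integer(0); b <- integer(0); sc <- numeric(0)
  repeat {
    if (length(a) >= min(nA, nB)) break
    best <- max(m)
    if (!is.finite(best) || best < min_score) break
    hit <- which(m == best)
    # column-major: lowest column then row; enforce lowest row first
    rows <- (hit - 1L) %% nA + 1L
    cols <- (hit - 1L) %/% nA + 1L
    pick <- order(rows, cols)[1]
    i <- rows[pick]; j <- cols[pick]
    a <- c(a, i); b <- c(b, j); sc <- c(sc, best)
    m[i, ] <- -Inf
    m[, j] <- -Inf
  }
  out <- tibble::tibble(a = a, b = b, score = sc)
  attr(out, "unmatched_a") <- setdiff(seq_len(nA), a)
  attr(out, "unmatched_b") <- setdiff(seq_len(nB), b)
  out
}
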