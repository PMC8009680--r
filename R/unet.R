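# Small 3D U-Net voxel classifier: a reduced encoder-decoder with two
# pooling levels (pooling in x-y only, respecting the axial anisotropy),
# 3x3x3 convolutions, ReLU activations and a sigmoid head, trained with
# binary cross-entropy and Adam. Feature maps are numeric arrays with
# dim (nz, ny, nx, C); convolutions run as im2col + GEMM through BLAS.

unet_conv_init <- function(cin, cout, k = c(3, 3, 3)) {
  fan_in <- cin * prod(k)
  list(W = matrix(stats::rnorm(cout * fan_in, 0, sqrt(2 / fan_in)), cout, fan_in),
       b = numeric(cout), k = as.integer(k), cin = cin, cout = cout)
}

unet_init <- function(nf = 8) {
  list(
    e1a = unet_conv_init(1, nf), e1b = unet_conv_init(nf, nf),
    e2a = unet_conv_init(nf, 2 * nf), e2b = unet_conv_init(2 * nf, 2 * nf),
    ba = unet_conv_init(2 * nf, 4 * nf), bb = unet_conv_init(4 * nf, 4 * nf),
    d2a = unet_conv_init(6 * nf, 2 * nf), d2b = unet_conv_init(2 * nf, 2 * nf),
    d1a = unet_conv_init(3 * nf, nf), d1b = unet_conv_init(nf, nf),
    out = unet_conv_init(nf, 1, k = c(1, 1, 1))
  )
}

conv_fwd <- function(x, dim3, layer) {
  cols <- cpp_im2col3d(x, c(dim3, layer$cin), layer$k)
  y <- layer$W %*% cols + layer$b
  list(y = as.numeric(t(y)), cols = cols) # (nvox-major per channel)
}

conv_bwd <- function(dy, cache, dim3, layer) {
  nvox <- prod(dim3)
  dym <- t(matrix(dy, nvox, layer$cout)) # cout x nvox
  dW <- tcrossprod(dym, cache$cols)
  db <- rowSums(dym)
  dx <- cpp_col2im3d(crossprod(layer$W, dym), c(dim3, layer$cin), layer$k)
  list(dx = as.numeric(dx), dW = dW, db = db)
}

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(dy, x) dy * (x > 0)

# max pool over (1, 2, 2); x has dim (nz, ny, nx, C) with even ny, nx
pool_fwd <- function(x, d4) {
  a <- array(x, d4)
  iy <- seq(1, d4[2], 2); ix <- seq(1, d4[3], 2)
  p1 <- a[, iy, ix, , drop = FALSE];     p2 <- a[, iy + 1, ix, , drop = FALSE]
  p3 <- a[, iy, ix + 1, , drop = FALSE]; p4 <- a[, iy + 1, ix + 1, , drop = FALSE]
  m <- pmax(p1, p2, p3, p4)
  list(y = as.numeric(m), which = cbind(as.numeric(p1) == as.numeric(m),
                                        as.numeric(p2) == as.numeric(m),
                                        as.numeric(p3) == as.numeric(m),
                                        as.numeric(p4) == as.numeric(m)),
       d4out = c(d4[1], d4[2] / 2, d4[3] / 2, d4[4]))
}

pool_bwd <- function(dy, cache, d4) {
  # route gradient to the first attaining position only
  w <- cache$which
  first <- w
  first[, 2] <- w[, 2] & !w[, 1]
  first[, 3] <- w[, 3] & !(w[, 1] | w[, 2])
  first[, 4] <- w[, 4] & !(w[, 1] | w[, 2] | w[, 3])
  dx <- array(0, d4)
  iy <- seq(1, d4[2], 2); ix <- seq(1, d4[3], 2)
  d4o <- cache$d4out
  g <- function(col) array(dy * first[, col], d4o)
  dx[, iy, ix, ]         <- g(1)
  dx[, iy + 1, ix, ]     <- g(2)
  dx[, iy, ix + 1, ]     <- g(3)
  dx[, iy + 1, ix + 1, ] <- g(4)
  as.numeric(dx)
}

upsample_fwd <- function(x, d4) {
  a <- array(x, d4)
  y <- a[, rep(seq_len(d4[2]), each = 2), rep(seq_len(d4[3]), each = 2), , drop = FALSE]
  list(y = as.numeric(y), d4out = c(d4[1], 2 * d4[2], 2 * d4[3], d4[4]))
}

upsample_bwd <- function(dy, d4in, d4out) {
  a <- array(dy, d4out)
  iy <- seq(1, d4out[2], 2); ix <- seq(1, d4out[3], 2)
  as.numeric(a[, iy, ix, , drop = FALSE] + a[, iy + 1, ix, , drop = FALSE] +
               a[, iy, ix + 1, , drop = FALSE] + a[, iy + 1, ix + 1, , drop = FALSE])
}

concat_c <- function(x1, x2) c(x1, x2) # channel-last layout: plain concat

# Full forward pass; returns sigmoid probabilities and, if `train`, the
# caches needed for backprop.
unet_forward <- function(W, x, dim3, train = FALSE) {
  cc <- list()
  d1 <- dim3
  c1 <- conv_fwd(x, d1, W$e1a); h1a <- relu_fwd(c1$y)
  c2 <- conv_fwd(h1a, d1, W$e1b); s1 <- relu_fwd(c2$y)
  nf <- W$e1a$cout
  p1 <- pool_fwd(s1, c(d1, nf))
  d2 <- p1$d4out[1:3]
  c3 <- conv_fwd(p1$y, d2, W$e2a); h2a <- relu_fwd(c3$y)
  c4 <- conv_fwd(h2a, d2, W$e2b); s2 <- relu_fwd(c4$y)
  p2 <- pool_fwd(s2, c(d2, 2 * nf))
  d3 <- p2$d4out[1:3]
  c5 <- conv_fwd(p2$y, d3, W$ba); h3a <- relu_fwd(c5$y)
  c6 <- conv_fwd(h3a, d3, W$bb); h3b <- relu_fwd(c6$y)
  u2 <- upsample_fwd(h3b, c(d3, 4 * nf))
  cat2 <- concat_c(s2, u2$y)
  c7 <- conv_fwd(cat2, d2, W$d2a); h4a <- relu_fwd(c7$y)
  c8 <- conv_fwd(h4a, d2, W$d2b); h4b <- relu_fwd(c8$y)
  u1 <- upsample_fwd(h4b, c(d2, 2 * nf))
  cat1 <- concat_c(s1, u1$y)
  c9 <- conv_fwd(cat1, d1, W$d1a); h5a <- relu_fwd(c9$y)
  c10 <- conv_fwd(h5a, d1, W$d1b); h5b <- relu_fwd(c10$y)
  c11 <- conv_fwd(h5b, d1, W$out)
  prob <- 1 / (1 + exp(-c11$y))
  if (!train) return(list(prob = prob))
  list(prob = prob,
       cache = list(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, c6 = c6,
                    c7 = c7, c8 = c8, c9 = c9, c10 = c10, c11 = c11,
                    h1a = h1a, s1 = s1, p1 = p1, h2a = h2a, s2 = s2, p2 = p2,
                    h3a = h3a, h3b = h3b, u2 = u2, h4a = h4a, h4b = h4b,
                    u1 = u1, h5a = h5a, h5b = h5b,
                    d1 = d1, d2 = d2, d3 = d3, nf = nf))
}

# Backprop of mean binary cross-entropy wrt all conv weights.
unet_backward <- function(W, fw, target) {
  K <- fw$cache
  n <- length(target)
  grads <- list()
  dlogit <- (fw$prob - target) / n
  g11 <- conv_bwd(dlogit, K$c11, K$d1, W$out); grads$out <- g11
  d <- relu_bwd(g11$dx, K$c10$y)
  g10 <- conv_bwd(d, K$c10, K$d1, W$d1b); grads$d1b <- g10
  d <- relu_bwd(g10$dx, K$c9$y)
  g9 <- conv_bwd(d, K$c9, K$d1, W$d1a); grads$d1a <- g9
  nf <- K$nf
  n1 <- prod(K$d1) * nf
  dskip1 <- g9$dx[seq_len(n1)]
  dup1 <- g9$dx[-seq_len(n1)]
  dh4b <- upsample_bwd(dup1, c(K$d2, 2 * nf), K$u1$d4out)
  d <- relu_bwd(dh4b, K$c8$y)
  g8 <- conv_bwd(d, K$c8, K$d2, W$d2b); grads$d2b <- g8
  d <- relu_bwd(g8$dx, K$c7$y)
  g7 <- conv_bwd(d, K$c7, K$d2, W$d2a); grads$d2a <- g7
  n2 <- prod(K$d2) * 2 * nf
  dskip2 <- g7$dx[seq_len(n2)]
  dup2 <- g7$dx[-seq_len(n2)]
  dh3b <- upsample_bwd(dup2, c(K$d3, 4 * nf), K$u2$d4out)
  d <- relu_bwd(dh3b, K$c6$y)
  g6 <- conv_bwd(d, K$c6, K$d3, W$bb); grads$bb <- g6
  d <- relu_bwd(g6$dx, K$c5$y)
  g5 <- conv_bwd(d, K$c5, K$d3, W$ba); grads$ba <- g5
  ds2 <- pool_bwd(g5$dx, K$p2, c(K$d2, 2 * nf))
  ds2 <- ds2 + dskip2
  d <- relu_bwd(ds2, K$c4$y)
  g4 <- conv_bwd(d, K$c4, K$d2, W$e2b); grads$e2b <- g4
  d <- relu_bwd(g4$dx, K$c3$y)
  g3 <- conv_bwd(d, K$c3, K$d2, W$e2a); grads$e2a <- g3
  ds1 <- pool_bwd(g3$dx, K$p1, c(K$d1, nf))
  ds1 <- ds1 + dskip1
  d <- relu_bwd(ds1, K$c2$y)
  g2 <- conv_bwd(d, K$c2, K$d1, W$e1b); grads$e1b <- g2
  d <- relu_bwd(g2$dx, K$c1$y)
  g1 <- conv_bwd(d, K$c1, K$d1, W$e1a); grads$e1a <- g1
  grads
}

unet_adam_step <- function(W, grads, state, lr = 1e-3, b1 = 0.9, b2 = 0.999,
                           eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    for (pp in c("W", "b")) {
      g <- if (pp == "W") grads[[nm]]$dW else grads[[nm]]$db
      key <- paste0(nm, ".", pp)
      if (is.null(state$m[[key]])) {
        state$m[[key]] <- g * 0
        state$v[[key]] <- g * 0
      }
      state$m[[key]] <- b1 * state$m[[key]] + (1 - b1) * g
      state$v[[key]] <- b2 * state$v[[key]] + (1 - b2) * g * g
      mh <- state$m[[key]] / (1 - b1^state$t)
      vh <- state$v[[key]] / (1 - b2^state$t)
      W[[nm]][[pp]] <- W[[nm]][[pp]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(W = W, state = state)
}

# Sample a training patch at `origin` (1-based (z,y,x)) with an optional
# random affine augmentation restricted to the x-y plane (rotation, scale,
# shear about the patch centre); image sampled trilinearly, labels nearest.
unet_sample_patch <- function(vol, lab, origin, pshape, augment = TRUE) {
  zr <- origin[1]:(origin[1] + pshape[1] - 1)
  yr <- origin[2]:(origin[2] + pshape[2] - 1)
  xr <- origin[3]:(origin[3] + pshape[3] - 1)
  if (!augment) {
    return(list(x = as.numeric(vol[zr, yr, xr]),
                y = as.numeric(lab[zr, yr, xr] > 0)))
  }
  theta <- stats::runif(1, -pi / 9, pi / 9)
  sc <- stats::runif(1, 0.9, 1.1)
  sh <- stats::runif(1, -0.1, 0.1)
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2) %*%
    matrix(c(sc, sh, 0, sc), 2, 2)
  cy <- mean(yr); cx <- mean(xr)
  grid <- expand.grid(z = zr, y = yr, x = xr)
  dyx <- cbind(grid$y - cy, grid$x - cx) %*% t(R)
  q <- cbind(grid$z, dyx[, 1] + cy, dyx[, 2] + cx)
  xs <- trilinear_at(vol, q)
  qn <- round(q)
  qn[, 1] <- pmin(pmax(qn[, 1], 1), dim(lab)[1])
  qn[, 2] <- pmin(pmax(qn[, 2], 1), dim(lab)[2])
  qn[, 3] <- pmin(pmax(qn[, 3], 1), dim(lab)[3])
  ys <- as.numeric(lab[qn] > 0)
  list(x = xs, y = ys)
}

train_unet3d <- function(vol, lab, patch_shape = c(8, 32, 32), nf = 8,
                         epochs = 20, patches_per_epoch = 8, lr = 1e-3,
                         augment = TRUE, holdout_fraction = 0.25,
                         seed = NULL, verbose = FALSE) {
  d <- dim(vol)
  if (any(d < patch_shape)) {
    stop("annotated volume is smaller than patch_shape", call. = FALSE)
  }
  if (any(patch_shape[2:3] %% 4 != 0)) {
    stop("patch y/x extents must be divisible by 4 (two pooling levels)",
         call. = FALSE)
  }
  with_seed(seed, {
    W <- unet_init(nf)
    state <- list(t = 0, m = list(), v = list())
    rand_origin <- function() {
      c(sample.int(d[1] - patch_shape[1] + 1, 1),
        sample.int(d[2] - patch_shape[2] + 1, 1),
        sample.int(d[3] - patch_shape[3] + 1, 1))
    }
    held <- lapply(seq_len(max(1, round(holdout_fraction * patches_per_epoch))),
                   function(i) unet_sample_patch(vol, lab, rand_origin(), patch_shape,
                                                 augment = FALSE))
    losses <- numeric(epochs)
    val_losses <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      tot <- 0
      for (it in seq_len(patches_per_epoch)) {
        p <- unet_sample_patch(vol, lab, rand_origin(), patch_shape, augment = augment)
        fw <- unet_forward(W, p$x, patch_shape, train = TRUE)
        pr <- pmin(pmax(fw$prob, 1e-7), 1 - 1e-7)
        tot <- tot + mean(-p$y * log(pr) - (1 - p$y) * log(1 - pr))
        grads <- unet_backward(W, fw, p$y)
        st <- unet_adam_step(W, grads, state, lr = lr)
        W <- st$W
        state <- st$state
      }
      losses[ep] <- tot / patches_per_epoch
      val_losses[ep] <- mean(vapply(held, function(p) {
        pr <- pmin(pmax(unet_forward(W, p$x, patch_shape)$prob, 1e-7), 1 - 1e-7)
        mean(-p$y * log(pr) - (1 - p$y) * log(1 - pr))
      }, numeric(1)))
      if (verbose) {
        message(sprintf("epoch %d: train BCE %.4f, held-out BCE %.4f",
                        ep, losses[ep], val_losses[ep]))
      }
    }
    list(weights = W, nf = nf, train_loss = losses, val_loss = val_losses)
  })
}
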