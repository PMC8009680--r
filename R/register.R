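#' Registration parameters
#'
#' Controls the EM-based non-rigid point-set registration that refines an
#' initial matching into a spatially coherent transformation. The moving
#' set is deformed as `T(x) = x + sum_k c_k exp(-||x - a_k||^2 / (2 beta^2))`
#' (a Gaussian-kernel displacement field anchored at the moving points),
#' so `beta` sets the coherence length of the motion -- neighbouring cells
#' are forced to move similarly over that scale -- and `lam` penalises
#' rough fields.
#'
#' @param beta Gaussian kernel width, in the coordinate units of the point
#'   sets (micrometres here; default 20).
#' @param lam regularization weight of the displacement field
#'   (default 0.01).
#' @param max_iter maximum EM iterations (default 20).
#' @param rematch_every recompute the initial matching every this many
#'   iterations via the caller-provided rematcher (NULL: match once
#'   before EM, the default; 10 is useful for very large movements).
#' @param outlier_weight uniform-outlier mixture weight in `[0, 1)`
#'   (default 0.1); absorbs detections with no counterpart.
#' @param tol convergence tolerance: stop when the mean displacement
#'   update falls below `tol` times the set diameter (default 1e-4).
#' @param sigma2_init optional fixed initial mixture variance; by default
#'   it is estimated from the residuals of the initial matching.
#' @param match_prior_weight prior probability mass put on an initially
#'   matched pair (default 0.7; the remainder follows the score matrix,
#'   so runner-up candidates can overturn a wrong greedy match).
#' @return A `registration_params` list.
#' @export
registration_params <- function(beta = 20, lam = 0.01, max_iter = 20,
                                rematch_every = NULL, outlier_weight = 0.1,
                                tol = 1e-4, sigma2_init = NULL,
                                match_prior_weight = 0.7) {
  stopifnot(beta > 0, lam >= 0, max_iter >= 1,
            outlier_weight >= 0, outlier_weight < 1)
  structure(list(beta = beta, lam = lam, max_iter = as.integer(max_iter),
                 rematch_every = rematch_every,
                 outlier_weight = outlier_weight, tol = tol,
                 sigma2_init = sigma2_init,
                 match_prior_weight = match_prior_weight),
            class = "registration_params")
}

# Build the component-prior matrix (nA x nB, columns sum to 1) from an
# initial matching (tibble a,b,score) or a full score matrix. When the
# matcher's full score matrix is available it supplies the residual prior
# mass, so runner-up candidates keep their standing instead of being
# flattened to uniform.
match_prior <- function(init, nA, nB, gamma = 0.9, scores = NULL) {
  if (is.matrix(init)) {
    return(sweep(init + 1e-12, 2, colSums(init + 1e-12), "/"))
  }
  base <- if (!is.null(scores)) {
    sweep(scores + 1e-6, 2, colSums(scores + 1e-6), "/")
  } else {
    matrix(1 / nA, nA, nB)
  }
  Pm <- base
  if (nrow(init) > 0) {
    for (r in seq_len(nrow(init))) {
      j <- init$b[r]; i <- init$a[r]
      rest <- base[, j]
      rest[i] <- 0
      s <- sum(rest)
      Pm[, j] <- if (s > 0) (1 - gamma) * rest / s else 0
      Pm[i, j] <- gamma
    }
  }
  Pm
}

#' Non-rigid registration of two point sets (EM refinement)
#'
#' Alternates (E) posterior correspondence probabilities of each moving
#' point to each target point under an isotropic Gaussian mixture centred
#' at the transformed moving points, with a uniform outlier component and
#' the initial matching injected as prior weights, and (M) a
#' lambda-regularized Gaussian-kernel least-squares solve for the
#' displacement coefficients. The mixture variance is re-estimated each
#' iteration from the weighted residuals.
#'
#' @param setA moving point set (the tracked positions).
#' @param setB target point set (the detected centres).
#' @param init initial matching: a [greedy_match()] tibble or a full
#'   score matrix.
#' @param params a [registration_params()].
#' @param rematcher optional `function(moved_points, setB)` returning a
#'   new initial matching; invoked every `rematch_every` iterations.
#' @param scores optional full similarity matrix from [score_pairs()];
#'   used as the residual prior mass behind the matched pairs.
#' @return A `prgls_transform` with fields `anchors`, `coefficients`,
#'   `beta`, `sigma2`, `n_iter`.
#' @export
register <- function(setA, setB, init, params = registration_params(),
                     rematcher = NULL, scores = NULL) {
  A <- as_point_matrix(setA)
  B <- as_point_matrix(setB)
  nA <- nrow(A); nB <- nrow(B)
  stopifnot(nA >= 1, nB >= 1)
  beta <- params$beta
  G <- exp(-cross_dist2(A, A) / (2 * beta^2))
  Pm <- match_prior(init, nA, nB, params$match_prior_weight, scores)
  diam <- sqrt(max(cross_dist2(rbind(A, B), rbind(A, B))))
  if (diam <= 0) diam <- 1
  sigma2 <- params$sigma2_init
  if (is.null(sigma2)) {
    if (!is.matrix(init) && nrow(init) > 0) {
      res <- rowSums((A[init$a, , drop = FALSE] - B[init$b, , drop = FALSE])^2)
      sigma2 <- max(mean(res) / 3, 1e-8 * diam^2)
    } else {
      d2 <- cross_dist2(A, B)
      sigma2 <- max(mean(apply(d2, 2, min)) / 3, 1e-8 * diam^2)
    }
  }
  # volume of the target bounding box, for the uniform outlier density
  rng <- apply(B, 2, range)
  V <- prod(pmax(rng[2, ] - rng[1, ], 1e-3))
  omega <- params$outlier_weight
  C <- matrix(0, nA, 3)
  TA <- A
  n_iter <- 0L
  for (iter in seq_len(params$max_iter)) {
    n_iter <- iter
    if (!is.null(params$rematch_every) && !is.null(rematcher) &&
        iter > 1 && (iter - 1) %% params$rematch_every == 0) {
      TA_pts <- TA
      attr(TA_pts, "ids") <- attr(A, "ids")
      rm_out <- rematcher(TA_pts, B)
      Pm <- match_prior(rm_out, nA, nB, params$match_prior_weight,
                        attr(rm_out, "scores"))
    }
    # E step
    D2 <- cross_dist2(TA, B)
    num <- Pm * exp(-D2 / (2 * sigma2))
    c_out <- if (omega > 0) {
      omega / (1 - omega) * (2 * pi * sigma2)^1.5 / V
    } else 0
    den <- colSums(num) + c_out
    den[den <= 0] <- Inf
    P <- sweep(num, 2, den, "/")
    # M step: (diag(d) G + lam sigma2 I) C = P B - diag(d) A
    d <- rowSums(P)
    lhs <- d * G
    diag(lhs) <- diag(lhs) + params$lam * sigma2
    rhs <- P %*% B - d * A
    Cnew <- tryCatch(solve(lhs, rhs), error = function(e) {
      warning("singular M-step system; adding ridge jitter")
      diag(lhs) <- diag(lhs) + 1e-8 * max(abs(diag(lhs))) + 1e-12
      solve(lhs, rhs)
    })
    upd <- mean(sqrt(rowSums((G %*% (Cnew - C))^2)))
    C <- Cnew
    TA <- A + G %*% C
    Np <- sum(P)
    if (Np > 0) {
      sigma2 <- max(sum(P * cross_dist2(TA, B)) / (3 * Np), 1e-10 * diam^2)
    }
    if (upd < params$tol * diam) break
  }
  structure(list(anchors = A, coefficients = C, beta = beta,
                 sigma2 = sigma2, n_iter = n_iter),
            class = "prgls_transform")
}

#' Apply a fitted transformation to points
#'
#' Evaluates `T(x) = x + sum_k c_k k(x, anchor_k)`; ordering and ids are
#' preserved.
#'
#' @param trans a `prgls_transform` from [register()].
#' @param pts points to move (matrix or data frame).
#' @return Matrix of transformed points (with the input ids attribute).
#' @export
apply_transform <- function(trans, pts) {
  m <- as_point_matrix(pts)
  K <- exp(-cross_dist2(m, trans$anchors) / (2 * trans$beta^2))
  out <- m + K %*% trans$coefficients
  colnames(out) <- c("z", "y", "x")
  attr(out, "ids") <- attr(m, "ids")
  out
}

#' @export
print.prgls_transform <- function(x, ...) {
  disp <- sqrt(rowSums((exp(-cross_dist2(x$anchors, x$anchors) /
                              (2 * x$beta^2)) %*% x$coefficients)^2))
  cat(sprintf("<prgls_transform> %d anchors, beta = %g, sigma = %.3g, %d EM iterations; mean |displacement| = %.3g\n",
              nrow(x$anchors), x$beta, sqrt(x$sigma2), x$n_iter, mean(disp)))
  invisible(x)
}
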