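test_that("the neighborhood descriptor has the documented structure", {
  set.seed(10)
  pts <- matrix(runif(35 * 3, 0, 60), 35, 3)
  f <- build_feature(7, pts)
  expect_length(f, 61)
  # triples sorted by non-decreasing magnitude; scale component positive
  mags <- sqrt(colSums(matrix(f[1:60], 3)^2))
  expect_true(all(diff(mags) >= -1e-12))
  expect_gt(f[61], 0)
  # mean of the 20 neighbor distances equals the last component
  d <- sqrt(colSums((t(pts) - pts[7, ])^2))
  expect_equal(f[61], mean(sort(d[-7])[1:20]))
  expect_error(build_feature(1, pts[1:20, ]), "21")
})

test_that("descriptors are translation- and scale-invariant as specified", {
  set.seed(11)
  pts <- matrix(runif(40 * 3, 0, 50), 40, 3)
  f <- build_feature(3, pts)
  expect_equal(build_feature(3, pts + 123.4), f, tolerance = 1e-12)
  f3 <- build_feature(3, pts * 3)
  expect_equal(f3[1:60], f[1:60], tolerance = 1e-9)
  expect_equal(f3[61], 3 * f[61], tolerance = 1e-9)
})

test_that("training gradients match numerical differentiation", {
  set.seed(12)
  net <- voltrackr:::ffn_init(hidden = 8L, seed = 3)
  n <- 6
  fa <- matrix(rnorm(n * 61), n, 61)
  fb <- matrix(rnorm(n * 61), n, 61)
  lab <- c(1, 0, 1, 0, 1, 0)
  loss_of <- function(net) {
    p <- voltrackr:::ffn_fwd_train(net, fa, fb)$p
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    mean(-lab * log(p) - (1 - lab) * log(1 - p))
  }
  fw <- voltrackr:::ffn_fwd_train(net, fa, fb)
  g <- voltrackr:::ffn_bwd(net, fw, fa, fb, lab)
  eps <- 1e-6
  for (chk in list(c("W1", 5), c("W2", 11), c("W3", 2), c("b2", 3))) {
    nm <- chk[1]; i <- as.integer(chk[2])
    np <- net; np[[nm]][i] <- np[[nm]][i] + eps
    nmi <- net; nmi[[nm]][i] <- nmi[[nm]][i] - eps
    num <- (loss_of(np) - loss_of(nmi)) / (2 * eps)
    expect_equal(unname(g[[nm]][i]), num, tolerance = 1e-4)
  }
  # batch-norm gamma gradient
  np <- net; np$bn1$gamma[2] <- np$bn1$gamma[2] + eps
  nmi <- net; nmi$bn1$gamma[2] <- nmi$bn1$gamma[2] - eps
  num <- (loss_of(np) - loss_of(nmi)) / (2 * eps)
  expect_equal(unname(g$bn1g[2]), num, tolerance = 1e-4)
})

test_that("training behaves like an optimizer and the outputs are probabilities", {
  base <- base_points_175()
  pairs <- generate_training_pairs(base, pair_gen_params(seed = 41), n_pairs = 4000)
  # untrained network already emits values strictly inside (0,1)
  net0 <- voltrackr:::ffn_init(hidden = 32L, seed = 5)
  s0 <- voltrackr:::ffn_score_features(net0, pairs$feature_a[1:50, ],
                                       pairs$feature_b[1:50, ])
  expect_true(all(s0 > 0 & s0 < 1))
  # loss decreases over epochs (fixed seed), deterministic given seed
  net <- train_ffn(pairs, epochs = 5, hidden = 64L, seed = 6)
  h <- tidy(net)
  expect_lt(h$train_loss[5], h$train_loss[1])
  net2 <- train_ffn(pairs, epochs = 5, hidden = 64L, seed = 6)
  expect_identical(net$W2, net2$W2)
  # single-class stream is rejected
  only_pos <- pairs[pairs$label == 1, ]
  expect_error(train_ffn(only_pos), "single class")
})

test_that("pairwise scoring equals the per-pair forward pass and is equivariant", {
  net <- shared_ffn()
  set.seed(13)
  A <- matrix(runif(25 * 3, 0, 40), 25, 3)
  B <- matrix(runif(30 * 3, 0, 40), 30, 3)
  S <- score_pairs(net, A, B)
  expect_equal(dim(S), c(25, 30))
  expect_true(all(S >= 0 & S <= 1))
  # matrix entries equal individually scored feature pairs
  fa <- voltrackr:::build_features_all(A)
  fb <- voltrackr:::build_features_all(B)
  idx <- cbind(c(1, 7, 25), c(3, 30, 14))
  direct <- voltrackr:::ffn_score_features(net, fa[idx[, 1], ], fb[idx[, 2], ])
  expect_equal(S[idx], direct, tolerance = 1e-10)
  # permuting B permutes the columns identically
  perm <- sample(30)
  S2 <- score_pairs(net, A, B[perm, ])
  expect_equal(S2, S[, perm], tolerance = 1e-10)
})

test_that("greedy matching follows the stated selection rule", {
  # worked 2x2 case: after (1,1) the remaining best 0.1 is below the cutoff
  m <- matrix(c(0.9, 0.85, 0.8, 0.1), 2, 2)
  res <- greedy_match(m, min_score = 0.5)
  expect_equal(nrow(res), 1)
  expect_equal(res$a, 1); expect_equal(res$b, 1); expect_equal(res$score, 0.9)
  expect_equal(attr(res, "unmatched_a"), 2L)
  expect_equal(attr(res, "unmatched_b"), 2L)
  # identity matrix gives the identity matching
  id <- diag(5)
  res <- greedy_match(id)
  expect_equal(res$a, res$b)
  # tie at the global max: lowest row, then lowest column, wins
  tie <- matrix(0.2, 3, 3)
  tie[2, 3] <- 0.9; tie[3, 1] <- 0.9; tie[2, 1] <- 0.9
  res <- greedy_match(tie)
  expect_equal(res$a[1], 2L)
  expect_equal(res$b[1], 1L)
})

test_that("greedy matching agrees with a brute-force re-implementation", {
  set.seed(14)
  for (rep in 1:5) {
    m <- matrix(runif(15 * 15), 15, 15)
    mine <- greedy_match(m, min_score = 0.3)
    oracle <- oracle_greedy(m, min_score = 0.3)
    expect_equal(as.matrix(mine[, c("a", "b", "score")]), oracle,
                 ignore_attr = TRUE)
  }
})

test_that("a trained matcher beats nearest-neighbour matching under large movements", {
  net <- shared_ffn()
  base <- base_points_175()
  # deformed copy carried by a bulk displacement (about 1.3x the typical
  # cell separation): well over 30% of movements have RM >= 0.5, which
  # defeats nearest-cell assignment, while the neighborhood descriptors
  # are translation-invariant
  set.seed(15)
  def <- deform_point_set(base, pair_gen_params())
  moved <- sweep(def$points, 2, c(0, 8, 8), "+")
  truth_rm <- sqrt(rowSums((moved - def$base_centered)^2)) /
    voltrackr:::nn_distance(moved)
  expect_gt(mean(truth_rm >= 0.5), 0.3)
  S <- score_pairs(net, moved, def$base_centered)
  mt <- greedy_match(S, 0.5)
  acc_ffn <- sum(mt$b == mt$a) / nrow(moved)
  nn <- apply(voltrackr:::cross_dist2(moved, def$base_centered), 1, which.min)
  acc_nn <- mean(nn == seq_len(nrow(moved)))
  expect_gt(acc_ffn, acc_nn)
})
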