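test_that("ensemble reference volumes follow the quotient schedule", {
  expect_identical(ensemble_refs(2), 1L)
  expect_identical(ensemble_refs(21), 20:1)
  expect_identical(ensemble_refs(101), as.integer(101 - 5 * (1:20)))
  expect_identical(ensemble_refs(101)[20], 1L)
  expect_error(ensemble_refs(1), "t >= 2")
  # property: length min(t-1, 20), indices >= 1 and strictly decreasing
  set.seed(41)
  for (t in c(2:30, sample.int(1e6, 40) + 1)) {
    r <- ensemble_refs(t)
    expect_length(r, min(t - 1, 20))
    expect_true(all(r >= 1))
    expect_true(all(diff(r) < 0))
  }
  # with one reference the schedule reduces to the single-mode predecessor
  expect_identical(ensemble_refs(57, max_refs = 1), 56L)
})

test_that("accurate correction converges onto an isolated blob", {
  d <- c(8, 32, 32)
  sp <- c(2, 0.5, 0.5)
  prob <- array(0, d)
  prob[3:5, 12:18, 12:18] <- 0.95
  pv <- image_volume(prob, sp)
  # template: a matching box region
  lab <- array(0L, d)
  lab[3:5, 12:18, 12:18] <- 1L
  tlab <- label_volume(lab, sp)
  true_ctr <- c(mean(2:4) * 2, mean(11:17) * 0.5, mean(11:17) * 0.5)
  # already centred: converges immediately, zero shift
  p0 <- matrix(true_ctr, 1, 3)
  attr(p0, "ids") <- 1L
  cfg <- tracker_config(correction_max_iter = 20, correction_tol = 0.01)
  out <- accurate_correct(p0, pv, tlab, cfg)
  expect_lt(sqrt(sum((out$positions - true_ctr)^2)), 0.01)
  # offset 2 um: pulled back to the centroid within tolerance
  p1 <- matrix(true_ctr + c(0, 2, 0), 1, 3)
  attr(p1, "ids") <- 1L
  out <- accurate_correct(p1, pv, tlab, cfg)
  expect_lt(sqrt(sum((out$positions - true_ctr)^2)), 0.35)
  expect_true(out$corrected)
  # a prediction far from any cell-like voxel is flagged, not moved
  p2 <- matrix(c(6, 2, 2), 1, 3)
  attr(p2, "ids") <- 1L
  out <- accurate_correct(p2, pv, tlab, cfg)
  expect_false(out$corrected[1])
  expect_equal(out$positions[1, ], c(6, 2, 2), ignore_attr = TRUE)
})

test_that("colliding placements are re-separated by watershed", {
  d <- c(8, 32, 48)
  sp <- c(2, 0.5, 0.5)
  prob <- array(0, d)
  prob[3:5, 12:18, 14:30] <- 0.95 # one elongated blob
  pv <- image_volume(prob, sp)
  lab <- array(0L, d)
  lab[3:5, 12:18, 14:19] <- 1L
  lab[3:5, 12:18, 25:30] <- 2L
  tlab <- label_volume(lab, sp)
  # both cells predicted onto the same end of the blob
  preds <- rbind(c(6, 7.5, 9.2), c(6, 7.5, 10.8))
  attr(preds, "ids") <- c(1L, 2L)
  cfg <- tracker_config(correction_max_iter = 3)
  out <- accurate_correct(preds, pv, tlab, cfg)
  l <- as.integer(out$labels)
  expect_setequal(setdiff(unique(l), 0L), c(1L, 2L))
  # each corrected centre lies in its own region
  for (i in 1:2) {
    cv <- round(out$positions[i, ] / sp) + 1
    expect_equal(out$labels[cv[1], cv[2], cv[3]], i)
  }
  # the two regions are disjoint by construction of a labeling
  expect_equal(sum(l == 1L) + sum(l == 2L), sum(l > 0L))
})

test_that("relative movement matches the brute-force oracle", {
  set.seed(42)
  tracks <- tidyr::expand_grid(cell_id = 1:8, t = 1:5)
  tracks$z_um <- runif(nrow(tracks), 0, 20)
  tracks$y_um <- runif(nrow(tracks), 0, 50)
  tracks$x_um <- runif(nrow(tracks), 0, 50)
  mine <- compute_rm(tracks)
  oracle <- oracle_rm(tracks)
  merged <- merge(mine, oracle, by = c("cell_id", "t"))
  expect_equal(nrow(merged), nrow(mine))
  expect_equal(merged$rm.x, merged$rm.y, tolerance = 1e-12)
})

test_that("tracking a static scene keeps every cell fixed with RM 0", {
  sc <- fixture("static_scene", function() {
    render_scene(scene_params(n_cells = 25, volume_shape = c(12, 80, 80),
                              n_volumes = 3, deformation_amplitude = 0,
                              activity_channel = FALSE, seed = 61))
  })
  lab1 <- sc$truth_labels[[1]]
  norm1 <- local_contrast_normalize(movie_frame(sc$movie, 1, 1), 50)
  clf <- train_classifier(norm1, lab1, "classical_threshold")
  res <- track_movie(sc$movie, lab1, clf, shared_ffn(),
                     tracker_config(keep_labels = FALSE))
  # positions constant within a fraction of the nearest-neighbour distance
  for (tt in 2:3) {
    p1 <- res$tracks[res$tracks$t == 1, c("z_um", "y_um", "x_um")]
    pt <- res$tracks[res$tracks$t == tt, c("z_um", "y_um", "x_um")]
    expect_lt(max(sqrt(rowSums((pt - p1)^2))), 1)
  }
  expect_lt(max(res$rm$rm), 0.2)
  expect_true(all(res$tracks$status == "tracked"))
  # cell count conservation
  expect_true(all(table(res$tracks$t) == res$n_cells))
})

test_that("skipped volumes carry positions forward", {
  sc <- small_scene()
  lab1 <- sc$truth_labels[[1]]
  clf <- small_scene_classifier()
  cfg <- tracker_config(skip_volumes = 3L, keep_labels = FALSE)
  res <- track_movie(sc$movie, lab1, clf, shared_ffn(), cfg)
  t2 <- res$tracks[res$tracks$t == 2, ]
  t3 <- res$tracks[res$tracks$t == 3, ]
  expect_equal(t3[, c("z_um", "y_um", "x_um")], t2[, c("z_um", "y_um", "x_um")],
               ignore_attr = TRUE)
  expect_true(all(t3$status == "carried_forward"))
  expect_true(all(res$rm$rm[res$rm$t == 3] == 0))
})

test_that("tracking results are reproducible and tidiable", {
  sc <- small_scene()
  lab1 <- sc$truth_labels[[1]]
  clf <- small_scene_classifier()
  res1 <- track_movie(sc$movie, lab1, clf, shared_ffn(),
                      tracker_config(keep_labels = FALSE))
  res2 <- track_movie(sc$movie, lab1, clf, shared_ffn(),
                      tracker_config(keep_labels = FALSE))
  expect_identical(res1$tracks, res2$tracks)
  td <- tidy(res1)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("cell_id", "t", "z_um", "status") %in% names(td)))
  g <- glance(res1)
  expect_identical(g$n_cells, res1$n_cells)
  expect_s3_class(autoplot(res1), "ggplot")
})
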