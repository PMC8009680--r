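test_that("simulated deformation obeys the affine-plus-noise construction", {
  base <- base_points_175()
  # zero half-widths: transformed set equals the mean-removed base exactly
  p0 <- pair_gen_params(affine_half_width = 0, small_noise_half_width = 0,
                        large_noise_half_width = 0, n_large_noise_points = 0)
  set.seed(1)
  def <- deform_point_set(base, p0)
  expect_equal(def$points[, 1:3], def$base_centered[, 1:3],
               ignore_attr = TRUE, tolerance = 1e-12)

  # default parameters: per-axis displacement bounded by the worst-case
  # affine term plus both noise half-widths; exactly 20 points carry the
  # large term
  set.seed(2)
  def <- deform_point_set(base, pair_gen_params())
  dd <- abs(def$points - def$base_centered)
  bound <- 0.05 * rowSums(abs(def$base_centered)) + 2 + 5
  expect_true(all(dd <= bound + 1e-12))
  expect_length(def$large_idx, 20)
  moved_far <- apply(dd, 1, max) > 2 + 0.05 * rowSums(abs(def$base_centered))
  expect_true(all(which(moved_far) %in% def$large_idx))

  # affine entries within bounds, mean near zero over many draws
  set.seed(3)
  us <- replicate(300, deform_point_set(base, pair_gen_params())$affine - diag(3))
  expect_true(all(abs(us) <= 0.05))
  expect_lt(abs(mean(us)), 3 * 0.05 / sqrt(length(us)))
})

test_that("training-pair generation is exact in label counts and reproducible", {
  base <- base_points_175()
  pairs <- generate_training_pairs(base, pair_gen_params(seed = 5), n_pairs = 10000)
  expect_identical(sum(pairs$label), 5000L)
  expect_identical(nrow(pairs), 10000L)
  expect_identical(ncol(pairs$feature_a), 61L)
  expect_true(all(is.finite(pairs$feature_a)), all(is.finite(pairs$feature_b)))
  # bit-reproducible under the same seed
  again <- generate_training_pairs(base, pair_gen_params(seed = 5), n_pairs = 10000)
  expect_identical(pairs, again)
  # uneven positive fraction still exact
  p25 <- generate_training_pairs(base, pair_gen_params(positive_fraction = 0.25,
                                                       seed = 6), n_pairs = 1000)
  expect_identical(sum(p25$label), 250L)
})

test_that("pair generation rejects invalid inputs", {
  small <- matrix(runif(60), 20, 3)
  expect_error(generate_training_pairs(small, n_pairs = 10), "at least 21")
  base <- matrix(runif(90), 30, 3)
  expect_error(
    generate_training_pairs(base, pair_gen_params(n_large_noise_points = 31),
                            n_pairs = 10),
    "exceeds")
})

test_that("rendered scenes carry consistent ground truth", {
  sc <- small_scene()
  expect_equal(sc$movie$n_time, 4)
  expect_equal(sc$movie$n_channel, 2)
  # cell count conserved over time
  counts <- table(sc$truth_tracks$t)
  expect_true(all(counts == 40))
  # truth positions match label centroids within half a voxel (max spacing)
  ctr <- centers_of(sc$truth_labels[[2]])
  tru <- sc$truth_tracks[sc$truth_tracks$t == 2, ]
  tru <- tru[order(tru$cell_id), ]
  err <- sqrt((ctr$z_um - tru$z_um)^2 + (ctr$y_um - tru$y_um)^2 +
                (ctr$x_um - tru$x_um)^2)
  expect_lt(max(err), max(spacing_of(sc$truth_labels[[2]])))
  # byte-identical re-render under the same parameters
  sc2 <- render_scene(sc$params)
  expect_identical(sc$movie$frames[[3]][[1]], sc2$movie$frames[[3]][[1]])
  expect_identical(sc$truth_tracks, sc2$truth_tracks)
})

test_that("a static scene has constant tracks and zero RM", {
  sc <- render_scene(scene_params(n_cells = 25, volume_shape = c(8, 64, 64),
                                  n_volumes = 3, deformation_amplitude = 0,
                                  activity_channel = FALSE,
                                  truth_labels_at = 1, seed = 11))
  rm_tbl <- compute_rm(sc$truth_tracks)
  expect_true(all(rm_tbl$rm == 0))
  t1 <- sc$truth_tracks[sc$truth_tracks$t == 1, c("z_um", "y_um", "x_um")]
  t3 <- sc$truth_tracks[sc$truth_tracks$t == 3, c("z_um", "y_um", "x_um")]
  expect_equal(t1, t3, ignore_attr = TRUE)
})

test_that("a calibrated scene reaches the intended difficulty regime", {
  # per-step displacement about 0.4x the nearest-neighbour distance
  sc <- render_scene(scene_params(n_cells = 50, volume_shape = c(16, 128, 128),
                                  n_volumes = 8, deformation_amplitude = 3.4,
                                  activity_channel = FALSE,
                                  truth_labels_at = 1, seed = 12))
  rm_tbl <- compute_rm(sc$truth_tracks)
  expect_gt(median(rm_tbl$rm), 0.3)
  expect_lt(median(rm_tbl$rm), 0.5)
})

test_that("degradation modes match their definitions", {
  sc <- small_scene()
  m <- sc$movie
  # temporal_subsample(1) is the identity
  expect_identical(degrade(m, "temporal_subsample", k = 1)$frames, m$frames)
  # subsampling keeps volumes 1, 1+k, ...
  s2 <- degrade(m, "temporal_subsample", k = 3)
  expect_equal(s2$n_time, 2)
  expect_identical(s2$frames[[2]], m$frames[[4]])
  # z binning sums groups exactly and scales the z spacing
  zb <- degrade(m, "z_bin", factor = 2)
  expect_equal(zb$shape[1], m$shape[1] / 2)
  expect_equal(zb$spacing[1], m$spacing[1] * 2)
  v <- m$frames[[1]][[1]]
  expect_equal(zb$frames[[1]][[1]][3, , ], v[5, , ] + v[6, , ],
               ignore_attr = TRUE)
  expect_equal(sum(zb$frames[[1]][[1]]), sum(v)) # photon conservation
})

test_that("added Poisson noise hits the requested standard deviation", {
  flat <- movie(list(list(array(500, c(16, 96, 96)))), c(2, 0.5, 0.5))
  noisy <- degrade(flat, "poisson_noise", sd = 60, seed = 21)
  delta <- as.numeric(noisy$frames[[1]][[1]]) - 500
  expect_gt(length(delta), 1e5)
  expect_lt(abs(sd(delta) - 60) / 60, 0.05)
  expect_lt(abs(mean(delta)), 1) # zero-mean adjusted
  expect_true(all(as.numeric(noisy$frames[[1]][[1]]) >= 0))
})
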