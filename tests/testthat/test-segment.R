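test_that("classifier contract: probabilities in [0,1], shape preserved", {
  sc <- small_scene()
  clf <- small_scene_classifier()
  norm <- local_contrast_normalize(movie_frame(sc$movie, 2, 1), 50)
  prob <- predict_probability(clf, norm)
  expect_identical(dim(prob), dim(norm))
  expect_true(all(prob >= 0 & prob <= 1))
  # near-zero input: background probability is low everywhere
  flat <- image_volume(array(0, c(8, 32, 32)), c(2, 0.5, 0.5))
  expect_lt(max(predict_probability(clf, flat)), 0.5)
})

test_that("classical backend separates a synthetic scene well", {
  sc <- small_scene()
  clf <- small_scene_classifier()
  # voxelwise F1 against the truth foreground on the training volume
  expect_gte(clf$state$f1, 0.9)
  # and on an unseen volume of the same scene
  norm <- local_contrast_normalize(movie_frame(sc$movie, 3, 1), 50)
  p <- as.numeric(predict_probability(clf, norm)) > 0.5
  fg <- as.numeric(sc$truth_labels[[3]]) > 0
  f1 <- 2 * sum(p & fg) / (sum(p) + sum(fg))
  expect_gte(f1, 0.9)
})

test_that("stitched tile prediction equals single-shot prediction at patch size", {
  clf <- small_scene_classifier()
  sc <- small_scene()
  norm <- local_contrast_normalize(movie_frame(sc$movie, 1, 1), 50)
  a <- unclass(norm); attributes(a) <- list(dim = dim(norm))
  block <- image_volume(a[1:8, 1:32, 1:32], c(2, 0.5, 0.5))
  clf_small <- clf
  clf_small$patch_shape <- c(8L, 32L, 32L)
  stitched <- predict_probability(clf_small, block)
  single <- voltrackr:::predict_patch(clf_small, unclass(block))
  expect_equal(as.numeric(stitched), as.numeric(single), tolerance = 1e-12)
})

test_that("watershed instances partition the mask and respect the size floor", {
  sc <- small_scene()
  clf <- small_scene_classifier()
  norm <- local_contrast_normalize(movie_frame(sc$movie, 1, 1), 50)
  prob <- predict_probability(clf, norm)
  seg <- instance_segment(prob, min_cell_size = 20)
  mask <- as.numeric(prob) > 0.5
  lab <- as.integer(seg)
  # labels only inside the mask
  expect_true(all(lab[!mask] == 0L))
  # consecutive positive labels
  ids <- setdiff(sort(unique(lab)), 0L)
  expect_identical(ids, seq_along(ids))
  # every surviving label has >= min_cell_size voxels and exactly one seed
  sizes <- tabulate(lab)
  expect_true(all(sizes[ids] >= 20))
  seeds <- attr(seg, "seeds")
  seed_labels <- lab[seeds]
  expect_identical(sort(seed_labels), seq_along(ids))
  # detected count within 5% of the true cell count
  expect_lte(abs(length(ids) - 40) / 40, 0.05)
})

test_that("probability threshold is strict at 0.5", {
  prob <- array(0.4, c(4, 12, 12))
  prob[2, 6, 6] <- 0.5 # boundary value stays background
  v <- image_volume(prob, c(1, 1, 1))
  expect_warning(seg <- instance_segment(v, min_cell_size = 1), "empty")
  expect_true(all(seg == 0L))
  prob[2, 6, 6] <- 0.500001
  v <- image_volume(prob, c(1, 1, 1))
  seg <- instance_segment(v, min_cell_size = 1)
  expect_equal(sum(seg > 0), 1)
  expect_equal(seg[2, 6, 6], 1L)
})

test_that("two overlapping blobs split into two labels owning their peaks", {
  d <- c(8, 40, 40)
  prob <- array(0, d)
  mk <- function(c0, r) {
    for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
      if (sum(((c(z, y, x) - c0) / r)^2) <= 1) prob[z, y, x] <<- 0.9
    }
  }
  c1 <- c(4, 14, 20); c2 <- c(4, 26, 20); r <- c(3, 8, 8)
  mk(c1, r); mk(c2, r) # centres 12 voxels apart in y, radius 8: heavy overlap
  v <- image_volume(prob, c(1, 1, 1))
  seg <- instance_segment(v, min_cell_size = 10)
  ids <- setdiff(unique(as.integer(seg)), 0L)
  expect_length(ids, 2)
  expect_true(seg[4, 14, 20] != seg[4, 26, 20])
  # boundary voxels split toward the nearer peak: check the midline bands
  expect_true(all(seg[4, 10:16, 18:22] == seg[4, 14, 20]))
  expect_true(all(seg[4, 24:30, 18:22] == seg[4, 26, 20]))
})

test_that("centroids agree with the brute-force oracle and the definition", {
  # single-voxel label at a known index
  lab <- array(0L, c(6, 8, 9))
  lab[3, 4, 5] <- 1L
  lv <- label_volume(lab, c(1.5, 0.16, 0.16))
  ctr <- centers_of(lv)
  expect_equal(unname(unlist(ctr[1, c("z_um", "y_um", "x_um")])),
               c(3.0, 0.48, 0.64))
  # random labels against per-voxel accumulation
  set.seed(31)
  lab <- array(sample(0:4, 6 * 8 * 9, replace = TRUE), c(6, 8, 9))
  lv <- label_volume(lab, c(2, 0.5, 0.5))
  got <- centers_of(lv)
  want <- oracle_centroids(lab, c(2, 0.5, 0.5))
  expect_equal(as.matrix(got), want, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("first-volume segmentations round-trip and are validated", {
  sc <- small_scene()
  lab <- sc$truth_labels[[1]]
  path <- withr::local_tempfile(fileext = ".tif")
  write_label_tiff(lab, path)
  back <- load_first_volume_segmentation(path, spacing_of(lab), dim(lab))
  expect_identical(array(as.integer(back), dim(back)),
                   array(as.integer(lab), dim(lab)))
  # shape mismatch is rejected
  expect_error(load_first_volume_segmentation(path, spacing_of(lab),
                                              c(8, 96, 96)), "match")
  # an all-background file is rejected
  zero <- label_volume(array(0L, c(4, 16, 16)), c(2, 0.5, 0.5))
  zpath <- withr::local_tempfile(fileext = ".tif")
  write_label_tiff(zero, zpath)
  expect_error(load_first_volume_segmentation(zpath, c(2, 0.5, 0.5)),
               "no cells")
  # a split label is accepted with a warning naming it
  splitlab <- array(0L, c(4, 16, 16))
  splitlab[2, 2:3, 2:3] <- 7L
  splitlab[2, 10:11, 10:11] <- 7L
  spath <- withr::local_tempfile(fileext = ".tif")
  write_label_tiff(label_volume(splitlab, c(2, 0.5, 0.5)), spath)
  expect_warning(load_first_volume_segmentation(spath, c(2, 0.5, 0.5)),
                 "disconnected.*7")
})

test_that("the small 3D U-Net backend trains and is a valid classifier", {
  sc <- fixture("unet_scene", function() {
    render_scene(scene_params(n_cells = 12, volume_shape = c(8, 64, 64),
                              n_volumes = 2, activity_channel = FALSE,
                              seed = 77))
  })
  norm1 <- local_contrast_normalize(movie_frame(sc$movie, 1, 1), 50)
  lab1 <- sc$truth_labels[[1]]
  # one epoch, no augmentation: still a valid classifier with outputs in [0,1]
  clf1 <- train_classifier(norm1, lab1, "unet3d_small",
                           patch_shape = c(8, 32, 32), epochs = 1,
                           augment = FALSE, seed = 51)
  p1 <- predict_probability(clf1, norm1)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # trained for longer: beats the classical backend on an unseen volume
  clf20 <- fixture("unet_trained", function() {
    train_classifier(norm1, lab1, "unet3d_small", patch_shape = c(8, 32, 32),
                     epochs = 20, patches_per_epoch = 16, seed = 52)
  })
  expect_lt(tail(clf20$state$val_loss, 1), clf20$state$val_loss[1])
  classical <- train_classifier(norm1, lab1, "classical_threshold")
  norm2 <- local_contrast_normalize(movie_frame(sc$movie, 2, 1), 50)
  fg <- as.numeric(sc$truth_labels[[2]]) > 0
  f1_of <- function(clf) {
    p <- as.numeric(predict_probability(clf, norm2)) > 0.5
    2 * sum(p & fg) / (sum(p) + sum(fg))
  }
  expect_gte(f1_of(clf20), f1_of(classical))
  # undersized annotation is rejected
  expect_error(train_classifier(image_volume(array(0.1, c(4, 16, 16)), c(2, .5, .5)),
                                label_volume(array(1L, c(4, 16, 16)), c(2, .5, .5)),
                                "unet3d_small", patch_shape = c(8, 32, 32)),
               "smaller")
})

test_that("prediction tracks a translated blob (U-Net, tiled)", {
  sc <- fixture("unet_scene", function() {
    render_scene(scene_params(n_cells = 12, volume_shape = c(8, 64, 64),
                              n_volumes = 2, activity_channel = FALSE,
                              seed = 77))
  })
  clf <- fixture("unet_trained", function() {
    norm1 <- local_contrast_normalize(movie_frame(sc$movie, 1, 1), 50)
    train_classifier(norm1, sc$truth_labels[[1]], "unet3d_small",
                     patch_shape = c(8, 32, 32), epochs = 20,
                     patches_per_epoch = 16, seed = 52)
  })
  norm1 <- local_contrast_normalize(movie_frame(sc$movie, 1, 1), 50)
  a <- unclass(norm1); attributes(a) <- list(dim = dim(norm1))
  shifted <- a
  shifted[, , 1:58] <- a[, , 7:64]
  shifted[, , 59:64] <- a[, , 1:6]
  pa <- as.numeric(predict_probability(clf, image_volume(a, c(2, .5, .5)))) > 0.5
  ps <- as.numeric(predict_probability(clf, image_volume(shifted, c(2, .5, .5)))) > 0.5
  cm <- function(mask) {
    idx <- which(array(mask, dim(a)), arr.ind = TRUE)
    colMeans(idx)
  }
  # centroid of the probability mass shifts by ~6 voxels in x only
  d <- cm(ps) - cm(pa)
  expect_lt(abs(d[1]), 1)
  expect_lt(abs(d[2]), 1)
  expect_lt(abs(d[3] + 6), 1)
})
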