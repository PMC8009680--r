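# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# A small, quick scene shared by segmentation/tracking unit tests.
small_scene <- function() {
  fixture("small_scene", function() {
    render_scene(scene_params(n_cells = 40, volume_shape = c(16, 96, 96),
                              n_volumes = 4, seed = 401))
  })
}

# A random, well-separated base point set (175 cells as in the reference
# configuration for matcher training).
base_points_175 <- function() {
  fixture("base_points_175", function() {
    set.seed(175)
    m <- matrix(runif(175 * 3), 175, 3)
    m[, 1] <- m[, 1] * 30   # z, um
    m[, 2] <- m[, 2] * 90   # y
    m[, 3] <- m[, 3] * 90   # x
    m
  })
}

# One modestly trained matcher shared across tests that need a working
# (not state-of-the-art) network.
shared_ffn <- function() {
  fixture("shared_ffn", function() {
    pairs <- generate_training_pairs(base_points_175(),
                                     pair_gen_params(seed = 31), n_pairs = 30000)
    train_ffn(pairs, epochs = 3, seed = 32)
  })
}

# Classifier trained on the small scene's first volume.
small_scene_classifier <- function() {
  fixture("small_scene_classifier", function() {
    sc <- small_scene()
    norm <- local_contrast_normalize(movie_frame(sc$movie, 1, 1), 50)
    train_classifier(norm, sc$truth_labels[[1]], "classical_threshold")
  })
}
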