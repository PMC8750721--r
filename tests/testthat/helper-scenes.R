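# Shared fixture builders. Everything is generated in code at test time.

# Small calyx-view scene configuration for fast end-to-end checks.
small_scene <- function(..., seed = 1) {
  scene_config(image_size = c(64, 64), n_bands = 24, apple_radius = 26,
               calyx_radius = 4, lesion_radius = 10, seed = seed, ...)
}

# A tiny cube with known values for I/O and indexing tests.
toy_cube <- function(H = 4, W = 5, B = 3, seed = 1) {
  set.seed(seed)
  hypercube(array(round(runif(H * W * B), 4), c(H, W, B)),
            seq(900, 1700, length.out = B), name = "toy")
}

# Feature matrix with the class signal confined to `bands` (mean shift).
band_confined_features <- function(n, B, bands, shift = 1.2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * B), n, B)
  y <- rep(c("healthy", "infested"), length.out = n)
  X[y == "infested", bands] <- X[y == "infested", bands] + shift
  list(X = X, y = y)
}
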