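# Shared fixtures. Heavier objects (tiny trained models, small datasets) are
# built once per test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

tiny_world <- function(...) {
  world_config(image_size = 16L, supersample = 1L, master_seed = 7L, ...)
}

# A 16-px bimodal dataset of 60 images.
tiny_dataset <- function() {
  fixture("tiny_dataset", function() {
    generate_dataset(tiny_world(), n = 60, seed = 301)
  })
}

tiny_vae_config <- function(epochs = 3L) {
  pixelvae_config(image_size = 16L, cond_widths = c(6L, 8L, 12L),
                  cond_fc = 32L, ar_blocks = 3L, ar_layers = 2L,
                  ar_maps = 8L, mixture_components = 3L, latent_dim = 6L,
                  epochs = epochs)
}

# A minimally trained tiny model: enough for mechanism tests (masking,
# encoding, generation, traversal), not for performance claims.
tiny_vae <- function() {
  fixture("tiny_vae", function() {
    train_pixelvae(tiny_dataset(), tiny_vae_config(epochs = 1L), seed = 5L)
  })
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")

with_seed_shuffle <- function(x) {
  glossim:::with_seed(99L, sample(x))
}
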