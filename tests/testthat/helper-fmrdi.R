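# Shared fixtures for the test suite. Everything is generated in code; the
# trained coarse-estimation model is expensive, so it is trained once per test
# run (lazily) and shared across test files.

.test_cache <- new.env(parent = emptyenv())

test_grid <- function() time_grid(75L, 5.0)

# Reduced-scale training run used throughout the suite: a small transformer
# (d_model 32, 2 heads, FFN 64) trained for 450 iterations of batch 48 at
# learning rate 1e-3 on the default synthetic conditions (fMRDI curves,
# SNR ~ U(4, 32)). Takes a few minutes on one core.
test_model <- function() {
  if (is.null(.test_cache$model)) {
    cfg <- model_config(d_model = 32L, n_heads = 2L, ffn_width = 64L)
    m <- build_model(cfg, seed = 11L)
    m <- train_model(m, tc = train_config(iterations = 450L, learning_rate = 1e-3,
                                          batch_size = 48L, seed = 7L))
    .test_cache$model <- m
  }
  .test_cache$model
}

# Noise-free fMRDI curves with their generating parameters.
noise_free_batch <- function(n, seed) {
  synthesize_batch(noise = NULL, grid = test_grid(), n = n, seed = seed)
}

# Relative l2 error between two curves.
rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))
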