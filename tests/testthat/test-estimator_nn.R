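# A tiny configuration keeps the architectural unit tests fast; the shared
# reduced-scale trained model (helper) backs the learning tests.
tiny_cfg <- function(...) {
  model_config(d_model = 8L, n_heads = 2L, ffn_width = 12L, n_layers = 2L,
               dropout = 0, seq_len = 12L, ...)
}

test_that("model configuration validates its invariants", {
  expect_error(model_config(d_model = 30L, n_heads = 4L), "divisible")
  expect_error(model_config(output_dim = 3L), "output_dim")
  expect_error(model_config(dropout = 1), "dropout")
  cfg <- model_config()
  expect_equal(cfg$input_dim, 80L)
  expect_equal(model_config(preprocess = "raw")$input_dim, 1L)
})

test_that("model outputs are nonnegative, shaped, and seed-deterministic", {
  cfg <- tiny_cfg()
  m1 <- build_model(cfg, seed = 5)
  m2 <- build_model(cfg, seed = 5)
  m3 <- build_model(cfg, seed = 6)
  set.seed(1)
  curves <- matrix(abs(rnorm(8 * 12)), 8, 12)
  p1 <- predict_pk(m1, curves)
  expect_equal(dim(p1), c(8L, 4L))
  expect_true(all(p1 >= 0))
  expect_true(all(p1[, "lambda_weight"] <= 1))
  expect_identical(p1, predict_pk(m2, curves))
  expect_false(identical(p1, predict_pk(m3, curves)))
  # inference is deterministic (no dropout at predict time)
  expect_identical(p1, predict_pk(m1, curves))
})

test_that("backpropagation matches finite differences on a smooth loss", {
  cfg <- tiny_cfg(preprocess = "raw")
  m <- build_model(cfg, seed = 3)
  set.seed(9)
  B <- 3L
  X <- matrix(rnorm(B * 12), ncol = 1)
  truth <- matrix(abs(rnorm(B * 4)), B, 4)
  fw <- fmrdi:::nn_forward(m, X, train = TRUE)
  grads <- fmrdi:::nn_backward(m, fw$cache, 2 * (fw$out - truth) / (4 * B))
  loss_of <- function(params) {
    m2 <- m; m2$params <- params
    mean((fmrdi:::nn_forward(m2, X)$out - truth)^2)
  }
  h <- 1e-5
  set.seed(2)
  for (nm in names(m$params)) {
    P <- m$params[[nm]]
    for (ii in sample(length(P), min(3, length(P)))) {
      pp <- m$params
      pp[[nm]][ii] <- P[ii] + h; up <- loss_of(pp)
      pp[[nm]][ii] <- P[ii] - h; dn <- loss_of(pp)
      fd <- (up - dn) / (2 * h)
      expect_lt(abs(grads[[nm]][ii] - fd) / max(1e-7, abs(fd)), 1e-4)
    }
  }
})

test_that("zero learning rate leaves the weights untouched", {
  g <- time_grid(12, 5)
  m <- build_model(tiny_cfg(), seed = 4)
  trained <- train_model(m, grid = g,
                         tc = train_config(iterations = 3L, learning_rate = 0,
                                           batch_size = 4L, seed = 2))
  expect_identical(trained$params, m$params)
  expect_length(trained$history, 3L)
})

test_that("checkpoints round-trip predictions bitwise", {
  m <- test_model()
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  ho <- noise_free_batch(20, seed = 5150)
  expect_identical(predict_pk(m2, ho$curves), predict_pk(m, ho$curves))
})

test_that("reduced training clearly improves on the untrained model", {
  m <- test_model()
  untrained <- build_model(m$config, seed = 11L)
  ho <- synthesize_batch(n = 200, seed = 865311)
  err_trained <- fmrdi:::nn_l1_error(m, ho$curves, ho$params)
  err_untrained <- fmrdi:::nn_l1_error(untrained, ho$curves, ho$params)
  expect_lt(err_trained, 0.5 * err_untrained)
})

test_that("training loss decreases across smoothed windows", {
  m <- test_model()
  h <- m$history
  win <- vapply(1:9, function(w) mean(h[((w - 1) * 50 + 1):(w * 50)]), 0)
  # smoothed loss at the end well below the start, and mostly monotone
  expect_lt(win[9], win[1])
  expect_gte(mean(diff(win) < 0), 0.7)
})

test_that("coarse estimates recover parameters on noise-free curves", {
  m <- test_model()
  ho <- noise_free_batch(500, seed = 99991)
  pred <- predict_pk(m, ho$curves)
  expect_true(all(pred >= 0))
  expect_true(all(pred[, "lambda_weight"] <= 1))
  rel <- sqrt((pred[, "ktrans"] - ho$params$ktrans)^2 +
                (pred[, "kep"] - ho$params$kep)^2) /
    sqrt(ho$params$ktrans^2 + ho$params$kep^2)
  expect_lt(median(rel), 0.3)
})

test_that("training aborts with a diagnostic when the loss diverges", {
  g <- time_grid(12, 5)
  m <- build_model(tiny_cfg(), seed = 4)
  m$params$Wh2[] <- Inf
  expect_error(
    train_model(m, grid = g, tc = train_config(iterations = 2L, batch_size = 4L)),
    "diverged"
  )
})
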