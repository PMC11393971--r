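#' Transformer model configuration
#'
#' Architecture of the coarse-estimation network: an input projection from the
#' preprocessed feature dimension to `d_model`, a learned positional
#' embedding, three pre-norm transformer encoder layers (multi-head
#' self-attention + feed-forward), mean pooling over time and a two-layer
#' regression head with a final ReLU so all four parameter estimates are
#' nonnegative.
#'
#' @param d_model Embedding width (default 64); must be divisible by
#'   `n_heads`.
#' @param n_heads Attention heads (default 4).
#' @param ffn_width Feed-forward hidden width (default 128).
#' @param n_layers Number of transformer layers (default 3).
#' @param dropout Dropout rate during training (default 0.1).
#' @param seq_len Input series length (default 75).
#' @param preprocess `"pyramid_sinusoidal"` (the default input transforms) or
#'   `"raw"` (feed the bare curve; used for ablations).
#' @param sigmas,omega0,n_freq Preprocessing parameters, stored with the model
#'   so checkpoints are self-describing.
#' @param output_dim Number of regressed parameters (4: ktrans, kep, t0,
#'   lambda).
#' @return An object of class `model_config`.
#' @export
model_config <- function(d_model = 64L, n_heads = 4L, ffn_width = 128L,
                         n_layers = 3L, dropout = 0.1, seq_len = 75L,
                         preprocess = c("pyramid_sinusoidal", "raw"),
                         sigmas = c(0, 2, 4, 8, 10), omega0 = 2 * pi / 100,
                         n_freq = 8L, output_dim = 4L) {
  preprocess <- match.arg(preprocess)
  d_model <- as.integer(d_model); n_heads <- as.integer(n_heads)
  if (d_model %% n_heads != 0L) stop("`d_model` must be divisible by `n_heads`", call. = FALSE)
  if (output_dim != 4L) stop("`output_dim` must be 4", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("`dropout` must be in [0, 1)", call. = FALSE)
  input_dim <- if (preprocess == "raw") 1L else length(sigmas) * 2L * as.integer(n_freq)
  structure(list(d_model = d_model, n_heads = n_heads,
                 ffn_width = as.integer(ffn_width), n_layers = as.integer(n_layers),
                 dropout = dropout, seq_len = as.integer(seq_len),
                 preprocess = preprocess, sigmas = sigmas, omega0 = omega0,
                 n_freq = as.integer(n_freq), input_dim = input_dim,
                 output_dim = 4L),
            class = "model_config")
}

#' Training configuration
#'
#' The coarse estimator is trained on freshly synthesized batches (an
#' effectively unlimited training set), minimizing the mean absolute error
#' between predicted and generating parameters with Adam. The loss is averaged
#' over the four parameters within each sample, then across the batch.
#'
#' @param iterations Training iterations (default 100000).
#' @param learning_rate Fixed Adam learning rate (default 1e-4).
#' @param batch_size Curves per iteration (default 256).
#' @param clip_norm Global gradient-norm clipping threshold (default 1; `Inf`
#'   disables clipping). Standard stabilization for transformer training.
#' @param seed Integer seed driving initialization-independent batch synthesis
#'   and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(iterations = 100000L, learning_rate = 1e-4,
                         batch_size = 256L, clip_norm = 1, seed = 1L) {
  if (iterations < 1 || batch_size < 1 || learning_rate < 0 || clip_norm <= 0) {
    stop("`iterations` and `batch_size` must be >= 1, `learning_rate` >= 0 and `clip_norm` > 0",
         call. = FALSE)
  }
  structure(list(iterations = as.integer(iterations), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), clip_norm = clip_norm,
                 seed = as.integer(seed)),
            class = "train_config")
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Build an untrained coarse-estimation model
#'
#' @param cfg A [model_config()].
#' @param seed Initialization seed; identical seeds give identical weights.
#' @return An object of class `fmrdi_nn` holding the configuration and weight
#'   list.
#' @export
build_model <- function(cfg = model_config(), seed = 1L) {
  if (!inherits(cfg, "model_config")) stop("`cfg` must be a `model_config`", call. = FALSE)
  d <- cfg$d_model; f <- cfg$ffn_width
  p <- with_seed(seed, {
    par <- list(
      W_in = glorot(cfg$input_dim, d), b_in = numeric(d),
      pos = matrix(stats::rnorm(cfg$seq_len * d, 0, 0.02), cfg$seq_len, d)
    )
    for (l in seq_len(cfg$n_layers)) {
      pre <- sprintf("l%d_", l)
      par[[paste0(pre, "ln1_g")]] <- rep(1, d)
      par[[paste0(pre, "ln1_b")]] <- numeric(d)
      par[[paste0(pre, "Wq")]] <- glorot(d, d); par[[paste0(pre, "bq")]] <- numeric(d)
      par[[paste0(pre, "Wk")]] <- glorot(d, d); par[[paste0(pre, "bk")]] <- numeric(d)
      par[[paste0(pre, "Wv")]] <- glorot(d, d); par[[paste0(pre, "bv")]] <- numeric(d)
      par[[paste0(pre, "Wo")]] <- glorot(d, d); par[[paste0(pre, "bo")]] <- numeric(d)
      par[[paste0(pre, "ln2_g")]] <- rep(1, d)
      par[[paste0(pre, "ln2_b")]] <- numeric(d)
      par[[paste0(pre, "W1")]] <- glorot(d, f); par[[paste0(pre, "b1")]] <- numeric(f)
      par[[paste0(pre, "W2")]] <- glorot(f, d); par[[paste0(pre, "b2")]] <- numeric(d)
    }
    par$lnf_g <- rep(1, d); par$lnf_b <- numeric(d)
    par$Wh1 <- glorot(d, f); par$bh1 <- numeric(f)
    par$Wh2 <- glorot(f, cfg$output_dim)
    # start the ReLU head at the default prior means so no output is born dead
    par$bh2 <- c(0.114, 0.667, 0.05, 0.5)
    par
  })
  structure(list(config = cfg, params = p, history = numeric(0)), class = "fmrdi_nn")
}

#' @export
print.fmrdi_nn <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<fmrdi_nn> %d layers, d_model %d, %d heads, %d parameters, %s\n",
              x$config$n_layers, x$config$d_model, x$config$n_heads, np,
              if (length(x$history)) sprintf("trained %d iterations", length(x$history))
              else "untrained"))
  invisible(x)
}

# ---- layer primitives ------------------------------------------------------

add_bias <- function(X, b) X + rep(b, each = nrow(X))

# Hidden layers use a leaky rectifier (slope 0.01 below zero) so units cannot
# die during short training runs; the output activation remains a plain ReLU.
# Leaky output sign equals input sign, so the backward mask derives from it.
leaky_relu <- function(x) pmax(x, 0) + 0.01 * pmin(x, 0)
leaky_mask <- function(r) (r > 0) + 0.01 * (r <= 0)

ln_fwd <- function(X, g, b, eps = 1e-5) {
  m <- rowMeans(X)
  xc <- X - m
  s <- sqrt(rowMeans(xc * xc) + eps)
  xh <- xc / s
  list(y = add_bias(xh * rep(g, each = nrow(X)), b), xh = xh, s = s)
}

ln_bwd <- function(dY, cache, g) {
  xh <- cache$xh
  dxh <- dY * rep(g, each = nrow(dY))
  dx <- (dxh - rowMeans(dxh) - xh * rowMeans(dxh * xh)) / cache$s
  list(dx = dx, dg = colSums(dY * xh), db = colSums(dY))
}

# ---- forward / backward ----------------------------------------------------

# X: (B*L) x input_dim feature matrix, rows grouped by sample (L consecutive
# rows per curve). Returns predictions and, when `train`, the cache needed for
# backprop. Dropout draws from the current RNG stream.
nn_forward <- function(model, X, train = FALSE) {
  cfg <- model$config
  p <- model$params
  L <- cfg$seq_len
  BL <- nrow(X)
  if (BL %% L != 0L) stop("feature rows must be a multiple of `seq_len`", call. = FALSE)
  B <- BL %/% L
  nh <- cfg$n_heads
  dh <- cfg$d_model %/% nh
  scale <- 1 / sqrt(dh)
  drop_p <- if (train) cfg$dropout else 0
  row_slices <- lapply(seq_len(B), function(b) ((b - 1L) * L + 1L):(b * L))
  col_slices <- lapply(seq_len(nh), function(h) ((h - 1L) * dh + 1L):(h * dh))
  cache <- if (train) list(X = X, B = B) else NULL

  H <- add_bias(X %*% p$W_in, p$b_in)
  H <- H + p$pos[rep(seq_len(L), B), , drop = FALSE]

  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("l%d_", l)
    lc <- list(H_in = H)
    n1 <- ln_fwd(H, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
    Q <- add_bias(n1$y %*% p[[paste0(pre, "Wq")]], p[[paste0(pre, "bq")]])
    K <- add_bias(n1$y %*% p[[paste0(pre, "Wk")]], p[[paste0(pre, "bk")]])
    V <- add_bias(n1$y %*% p[[paste0(pre, "Wv")]], p[[paste0(pre, "bv")]])
    O <- matrix(0, BL, cfg$d_model)
    Plist <- if (train) vector("list", B * nh)
    for (b in seq_len(B)) {
      rows <- row_slices[[b]]
      for (h in seq_len(nh)) {
        cols <- col_slices[[h]]
        S <- tcrossprod(Q[rows, cols, drop = FALSE], K[rows, cols, drop = FALSE]) * scale
        S <- exp(S - max(S))
        P <- S / rowSums(S)
        O[rows, cols] <- P %*% V[rows, cols, drop = FALSE]
        if (train) Plist[[(b - 1L) * nh + h]] <- P
      }
    }
    A <- add_bias(O %*% p[[paste0(pre, "Wo")]], p[[paste0(pre, "bo")]])
    if (drop_p > 0) {
      m1 <- matrix((stats::runif(length(A)) >= drop_p) / (1 - drop_p), BL, cfg$d_model)
      A <- A * m1
    } else m1 <- NULL
    H <- H + A
    lc2 <- list(H_mid = H)
    n2 <- ln_fwd(H, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]])
    Z1 <- add_bias(n2$y %*% p[[paste0(pre, "W1")]], p[[paste0(pre, "b1")]])
    R1 <- leaky_relu(Z1)
    F2 <- add_bias(R1 %*% p[[paste0(pre, "W2")]], p[[paste0(pre, "b2")]])
    if (drop_p > 0) {
      m2 <- matrix((stats::runif(length(F2)) >= drop_p) / (1 - drop_p), BL, cfg$d_model)
      F2 <- F2 * m2
    } else m2 <- NULL
    H <- H + F2
    if (train) {
      cache[[paste0(pre, "c")]] <- list(
        H_in = lc$H_in, n1 = n1, Q = Q, K = K, V = V, O = O, Plist = Plist,
        m1 = m1, H_mid = lc2$H_mid, n2 = n2, R1 = R1, m2 = m2)
    }
  }

  nf <- ln_fwd(H, p$lnf_g, p$lnf_b)
  M <- rowsum(nf$y, group = rep(seq_len(B), each = L), reorder = FALSE) / L
  Z_h1 <- add_bias(M %*% p$Wh1, p$bh1)
  R_h1 <- leaky_relu(Z_h1)
  Z_out <- add_bias(R_h1 %*% p$Wh2, p$bh2)
  out <- pmax(Z_out, 0)
  if (train) {
    cache$nf <- nf; cache$M <- M; cache$R_h1 <- R_h1
    cache$Z_out <- Z_out; cache$H_last <- H
  }
  list(out = out, cache = cache)
}

# Backward pass: dOut is the loss gradient at the (post-ReLU) output, B x 4.
# Returns the gradient list matching model$params.
nn_backward <- function(model, cache, dOut) {
  cfg <- model$config
  p <- model$params
  L <- cfg$seq_len
  B <- cache$B
  BL <- B * L
  nh <- cfg$n_heads
  dh <- cfg$d_model %/% nh
  scale <- 1 / sqrt(dh)
  row_slices <- lapply(seq_len(B), function(b) ((b - 1L) * L + 1L):(b * L))
  col_slices <- lapply(seq_len(nh), function(h) ((h - 1L) * dh + 1L):(h * dh))
  g <- list()

  dZ_out <- dOut * (cache$Z_out > 0)
  g$Wh2 <- crossprod(cache$R_h1, dZ_out)
  g$bh2 <- colSums(dZ_out)
  dR_h1 <- tcrossprod(dZ_out, p$Wh2)
  dZ_h1 <- dR_h1 * leaky_mask(cache$R_h1)
  g$Wh1 <- crossprod(cache$M, dZ_h1)
  g$bh1 <- colSums(dZ_h1)
  dM <- tcrossprod(dZ_h1, p$Wh1)
  dNf <- dM[rep(seq_len(B), each = L), , drop = FALSE] / L
  bw <- ln_bwd(dNf, cache$nf, p$lnf_g)
  g$lnf_g <- bw$dg; g$lnf_b <- bw$db
  dH <- bw$dx

  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- sprintf("l%d_", l)
    lc <- cache[[paste0(pre, "c")]]
    # FFN block
    dF2 <- if (!is.null(lc$m2)) dH * lc$m2 else dH
    g[[paste0(pre, "b2")]] <- colSums(dF2)
    g[[paste0(pre, "W2")]] <- crossprod(lc$R1, dF2)
    dR1 <- tcrossprod(dF2, p[[paste0(pre, "W2")]])
    dZ1 <- dR1 * leaky_mask(lc$R1)
    g[[paste0(pre, "b1")]] <- colSums(dZ1)
    g[[paste0(pre, "W1")]] <- crossprod(lc$n2$y, dZ1)
    dN2 <- tcrossprod(dZ1, p[[paste0(pre, "W1")]])
    bw <- ln_bwd(dN2, lc$n2, p[[paste0(pre, "ln2_g")]])
    g[[paste0(pre, "ln2_g")]] <- bw$dg; g[[paste0(pre, "ln2_b")]] <- bw$db
    dH <- dH + bw$dx
    # attention block
    dA <- if (!is.null(lc$m1)) dH * lc$m1 else dH
    g[[paste0(pre, "bo")]] <- colSums(dA)
    g[[paste0(pre, "Wo")]] <- crossprod(lc$O, dA)
    dO <- tcrossprod(dA, p[[paste0(pre, "Wo")]])
    dQ <- matrix(0, BL, cfg$d_model)
    dK <- matrix(0, BL, cfg$d_model)
    dV <- matrix(0, BL, cfg$d_model)
    for (b in seq_len(B)) {
      rows <- row_slices[[b]]
      for (h in seq_len(nh)) {
        cols <- col_slices[[h]]
        P <- lc$Plist[[(b - 1L) * nh + h]]
        dOb <- dO[rows, cols, drop = FALSE]
        dP <- tcrossprod(dOb, lc$V[rows, cols, drop = FALSE])
        dV[rows, cols] <- crossprod(P, dOb)
        dS <- P * (dP - rowSums(dP * P))
        dQ[rows, cols] <- (dS %*% lc$K[rows, cols, drop = FALSE]) * scale
        dK[rows, cols] <- crossprod(dS, lc$Q[rows, cols, drop = FALSE]) * scale
      }
    }
    n1y <- lc$n1$y
    g[[paste0(pre, "bq")]] <- colSums(dQ); g[[paste0(pre, "Wq")]] <- crossprod(n1y, dQ)
    g[[paste0(pre, "bk")]] <- colSums(dK); g[[paste0(pre, "Wk")]] <- crossprod(n1y, dK)
    g[[paste0(pre, "bv")]] <- colSums(dV); g[[paste0(pre, "Wv")]] <- crossprod(n1y, dV)
    dN1 <- tcrossprod(dQ, p[[paste0(pre, "Wq")]]) + tcrossprod(dK, p[[paste0(pre, "Wk")]]) +
      tcrossprod(dV, p[[paste0(pre, "Wv")]])
    bw <- ln_bwd(dN1, lc$n1, p[[paste0(pre, "ln1_g")]])
    g[[paste0(pre, "ln1_g")]] <- bw$dg; g[[paste0(pre, "ln1_b")]] <- bw$db
    dH <- dH + bw$dx
  }

  dHpos <- rowsum(dH, group = rep(seq_len(L), B), reorder = FALSE)
  g$pos <- dHpos
  g$b_in <- colSums(dH)
  g$W_in <- t(cache$X) %*% dH
  g
}

# Build the (B*L) x input_dim feature matrix for a batch of curves (rows =
# curves), applying the model's configured preprocessing.
nn_features <- function(cfg, curves) {
  if (is.vector(curves)) curves <- matrix(curves, nrow = 1L)
  B <- nrow(curves)
  L <- ncol(curves)
  if (L != cfg$seq_len) {
    stop(sprintf("curves have %d time points but the model expects %d", L, cfg$seq_len),
         call. = FALSE)
  }
  if (cfg$preprocess == "raw") {
    return(matrix(as.vector(t(curves)), ncol = 1L))
  }
  # batch trick: treat samples as channels (input-channel-major ordering keeps
  # each sample's block contiguous), then unfold to rows grouped by sample
  feats <- preprocess_curve(t(curves), sigmas = cfg$sigmas,
                            omega0 = cfg$omega0, n_freq = cfg$n_freq)
  fdim <- cfg$input_dim
  arr <- array(feats, dim = c(L, fdim, B))
  X <- aperm(arr, c(1L, 3L, 2L))
  dim(X) <- c(L * B, fdim)
  X
}

#' Coarse PK estimates from the network
#'
#' Runs the trained model in inference mode (no dropout). The ReLU head
#' guarantees nonnegative estimates; the dispersion weight is additionally
#' clipped to `[0, 1]`.
#'
#' @param model A trained `fmrdi_nn`.
#' @param curves Numeric vector (one curve) or matrix with one curve per row.
#' @param batch_size Curves per forward chunk (default 256).
#' @return A matrix with one row per curve and columns `ktrans`, `kep`, `t0`,
#'   `lambda_weight`.
#' @export
predict_pk <- function(model, curves, batch_size = 256L) {
  if (!inherits(model, "fmrdi_nn")) stop("`model` must be an `fmrdi_nn`", call. = FALSE)
  if (is.vector(curves)) curves <- matrix(curves, nrow = 1L)
  n <- nrow(curves)
  out <- matrix(0, n, 4L, dimnames = list(NULL, c("ktrans", "kep", "t0", "lambda_weight")))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    X <- nn_features(model$config, curves[idx, , drop = FALSE])
    out[idx, ] <- nn_forward(model, X, train = FALSE)$out
  }
  out[, "lambda_weight"] <- pmin(out[, "lambda_weight"], 1)
  out
}

# Mean absolute error of the model on given curves/parameters (per-sample mean
# over the 4 parameters, then averaged across curves).
nn_l1_error <- function(model, curves, params) {
  pred <- predict_pk(model, curves)
  truth <- as.matrix(params[, c("ktrans", "kep", "t0", "lambda_weight")])
  mean(rowMeans(abs(pred - truth)))
}

#' Train the coarse estimator on synthetic curves
#'
#' Every iteration draws a fresh synthetic batch (parameters from the prior,
#' fMRDI forward model, multiplicative noise), so the model never revisits a
#' training sample. Optimized with Adam at a fixed learning rate under the
#' mean-absolute-error loss. Aborts with a diagnostic if the loss diverges.
#'
#' @param model An `fmrdi_nn` from [build_model()].
#' @param prior A [prior_config()].
#' @param noise A [noise_config()].
#' @param grid A [time_grid()] (its length must match the model's `seq_len`).
#' @param tc A [train_config()].
#' @param verbose Print progress every 500 iterations.
#' @return The trained model, with the per-iteration loss history appended in
#'   `$history`.
#' @export
train_model <- function(model, prior = prior_config(), noise = noise_config(),
                        grid = time_grid(), tc = train_config(), verbose = FALSE) {
  if (!inherits(model, "fmrdi_nn")) stop("`model` must be an `fmrdi_nn`", call. = FALSE)
  if (!inherits(tc, "train_config")) stop("`tc` must be a `train_config`", call. = FALSE)
  assert_grid(grid)
  if (grid$n_points != model$config$seq_len) {
    stop("grid length must equal the model's `seq_len`", call. = FALSE)
  }
  p <- model$params
  mstate <- lapply(p, function(x) x * 0)
  vstate <- lapply(p, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- tc$learning_rate
  history <- numeric(tc$iterations)
  nms <- names(p)

  for (it in seq_len(tc$iterations)) {
    batch <- synthesize_batch(prior, noise, grid, n = tc$batch_size,
                              seed = child_seed(tc$seed, it))
    X <- nn_features(model$config, batch$curves)
    truth <- as.matrix(batch$params[, c("ktrans", "kep", "t0", "lambda_weight")])
    model$params <- p
    fw <- with_seed(child_seed(tc$seed, it + 500000), nn_forward(model, X, train = TRUE))
    diffm <- fw$out - truth
    loss <- mean(rowMeans(abs(diffm)))
    if (!is.finite(loss)) {
      stop(sprintf("training diverged at iteration %d (loss is not finite)", it),
           call. = FALSE)
    }
    history[it] <- loss
    dOut <- sign(diffm) / (4 * nrow(truth))
    grads <- nn_backward(model, fw$cache, dOut)
    if (is.finite(tc$clip_norm)) {
      gnorm <- sqrt(sum(vapply(grads, function(gi) sum(gi * gi), 0)))
      if (gnorm > tc$clip_norm) {
        sc <- tc$clip_norm / gnorm
        grads <- lapply(grads, function(gi) gi * sc)
      }
    }
    if (lr > 0) {
      corr1 <- 1 - b1^it
      corr2 <- 1 - b2^it
      for (nm in nms) {
        gi <- grads[[nm]]
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * gi
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * gi * gi
        p[[nm]] <- p[[nm]] - lr * (mstate[[nm]] / corr1) /
          (sqrt(vstate[[nm]] / corr2) + eps)
      }
    }
    if (verbose && it %% 500L == 0L) {
      message(sprintf("iter %d  loss %.5f", it, mean(history[max(1, it - 99):it])))
    }
  }
  model$params <- p
  model$history <- c(model$history, history)
  model
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles the weights, the architecture configuration and the
#' preprocessing parameters, so a loaded model reproduces predictions exactly.
#'
#' @param model An `fmrdi_nn`.
#' @param path File path.
#' @return `load_checkpoint()` returns the restored `fmrdi_nn`.
#' @export
save_checkpoint <- function(model, path) {
  if (!inherits(model, "fmrdi_nn")) stop("`model` must be an `fmrdi_nn`", call. = FALSE)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "fmrdi_nn")) stop("checkpoint does not contain an `fmrdi_nn`", call. = FALSE)
  model
}
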