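#' Time-series pyramid
#'
#' Convolves each input channel with unit-sum Gaussian kernels of increasing
#' width, stacking the smoothed versions as extra channels. The multiscale
#' stack suppresses noise and exposes context at several temporal scales. For
#' each `sigma` the kernel has `2*sigma + 1` taps and variance `sigma`
#' (truncated, then renormalized to unit sum); `sigma = 0` is the identity. Boundaries are handled by reflective padding, so constants are
#' preserved exactly. The transform is linear.
#'
#' Output channels are ordered input-channel-major, sigma-minor: for channel
#' `d` the block `(d, sigma_1), (d, sigma_2), ...`.
#'
#' @param x Numeric vector (length L) or `L x D` matrix of time series.
#' @param sigmas Kernel size parameters (default `c(0, 2, 4, 8, 10)`).
#' @return An `L x (D * length(sigmas))` matrix with a `channel_labels`
#'   attribute.
#' @export
time_series_pyramid <- function(x, sigmas = c(0, 2, 4, 8, 10)) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  if (!is.matrix(x) || !is.numeric(x) || !all(is.finite(x))) {
    stop("`x` must be a finite numeric vector or matrix", call. = FALSE)
  }
  if (any(sigmas < 0) || any(sigmas != round(sigmas))) {
    stop("`sigmas` must be nonnegative integers", call. = FALSE)
  }
  L <- nrow(x)
  D <- ncol(x)
  ns <- length(sigmas)
  out <- matrix(0, L, D * ns)
  for (si in seq_along(sigmas)) {
    sg <- sigmas[si]
    sm <- if (sg == 0) x else gauss_smooth(x, sg)
    out[, (seq_len(D) - 1L) * ns + si] <- sm
  }
  attr(out, "channel_labels") <- paste0(
    rep(sprintf("ch%d", seq_len(D)), each = ns), "_sigma", rep(sigmas, D))
  out
}

# Column-wise Gaussian smoothing with 2*sigma + 1 taps (variance = sigma,
# unit sum) and reflective padding (mirror about the boundary sample).
gauss_smooth <- function(x, sigma) {
  offs <- -sigma:sigma
  w <- exp(-offs^2 / (2 * sigma))
  w <- w / sum(w)
  L <- nrow(x)
  if (sigma >= L) stop("kernel wider than the series", call. = FALSE)
  idx <- c((sigma + 1L):2L, seq_len(L), (L - 1L):(L - sigma))
  xp <- x[idx, , drop = FALSE]
  out <- matrix(0, L, ncol(x))
  for (k in seq_along(offs)) {
    out <- out + w[k] * xp[(k - 1L) + seq_len(L), , drop = FALSE]
  }
  out
}

#' Sinusoidal normalization
#'
#' Maps every value `v` to the bounded vector
#' `(sin(1*w0*v), cos(1*w0*v), ..., sin(n_freq*w0*v), cos(n_freq*w0*v))`,
#' projecting the unnormalized, long-tailed concentration scale into a fixed
#' `[-1, 1]` range while keeping the mapping injective on `[0, 2*pi/w0)`.
#' With the default fundamental frequency `w0 = 2*pi/100` the injective range
#' is `[0, 100)`, far beyond physiological concentrations.
#'
#' Output channels are input-channel-major: for channel `d` the 2 * `n_freq`
#' block `(sin 1, cos 1, ..., sin n_freq, cos n_freq)`.
#'
#' @param x Numeric vector (length L) or `L x D` matrix.
#' @param omega0 Fundamental frequency, radians per concentration unit
#'   (default `2*pi/100`).
#' @param n_freq Number of harmonics (default 8).
#' @return An `L x (2 * n_freq * D)` matrix with values in `[-1, 1]`.
#' @export
sinusoidal_normalize <- function(x, omega0 = 2 * pi / 100, n_freq = 8L) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  if (!is.matrix(x) || !is.numeric(x) || !all(is.finite(x))) {
    stop("`x` must be a finite numeric vector or matrix", call. = FALSE)
  }
  if (!is.finite(omega0) || omega0 <= 0) stop("`omega0` must be > 0", call. = FALSE)
  n_freq <- as.integer(n_freq)
  if (n_freq < 1L) stop("`n_freq` must be >= 1", call. = FALSE)
  L <- nrow(x)
  D <- ncol(x)
  blk <- 2L * n_freq
  out <- matrix(0, L, D * blk)
  for (d in seq_len(D)) {
    base <- (d - 1L) * blk
    for (k in seq_len(n_freq)) {
      ang <- k * omega0 * x[, d]
      out[, base + 2L * k - 1L] <- sin(ang)
      out[, base + 2L * k] <- cos(ang)
    }
  }
  out
}

#' Preprocess a concentration curve for the neural network
#'
#' The composition of the two input transforms: the time-series pyramid
#' followed by sinusoidal normalization. A raw `L x 1` curve becomes an
#' `L x 80` feature matrix (`5` pyramid scales times `16` sinusoidal
#' channels).
#'
#' @param x Numeric vector (length L) or `L x D` matrix.
#' @param sigmas Pyramid kernel sizes.
#' @param omega0,n_freq Sinusoidal-normalization parameters.
#' @return An `L x (D * length(sigmas) * 2 * n_freq)` feature matrix.
#' @export
preprocess_curve <- function(x, sigmas = c(0, 2, 4, 8, 10),
                             omega0 = 2 * pi / 100, n_freq = 8L) {
  sinusoidal_normalize(time_series_pyramid(x, sigmas), omega0, n_freq)
}
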