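#' Priors for synthetic pharmacokinetic parameters
#'
#' Training curves are synthesized from parameters drawn from right-skewed
#' beta distributions (scaled to the physiological ranges) and a uniform
#' bolus-arrival jitter: `ktrans ~ scale_k * Beta(a_k, b_k)`,
#' `kep ~ scale_e * Beta(a_e, b_e)`, `lambda_weight ~ Beta(a_l, b_l)`,
#' `t0 ~ U(0, t0_max)` minutes.
#'
#' @param ktrans_scale,ktrans_shape Scale (1/min) and `c(a, b)` beta shapes
#'   for ktrans.
#' @param kep_scale,kep_shape Scale (1/min) and beta shapes for kep.
#' @param lambda_shape Beta shapes for the dispersion weight.
#' @param t0_max Upper bound of the uniform bolus-arrival prior, minutes.
#' @return An object of class `prior_config`.
#' @export
prior_config <- function(ktrans_scale = 0.4, ktrans_shape = c(2, 5),
                         kep_scale = 2.0, kep_shape = c(2, 4),
                         lambda_shape = c(1.5, 1.5), t0_max = 0.1) {
  shapes <- c(ktrans_shape, kep_shape, lambda_shape)
  if (length(ktrans_shape) != 2L || length(kep_shape) != 2L || length(lambda_shape) != 2L ||
      !all(is.finite(shapes)) || any(shapes <= 0)) {
    stop("beta shape parameters must be pairs of positive numbers", call. = FALSE)
  }
  if (!all(is.finite(c(ktrans_scale, kep_scale, t0_max))) ||
      ktrans_scale <= 0 || kep_scale <= 0 || t0_max < 0) {
    stop("scales must be > 0 and `t0_max` >= 0", call. = FALSE)
  }
  structure(list(ktrans_scale = ktrans_scale, ktrans_shape = ktrans_shape,
                 kep_scale = kep_scale, kep_shape = kep_shape,
                 lambda_shape = lambda_shape, t0_max = t0_max),
            class = "prior_config")
}

#' Multiplicative noise configuration
#'
#' Noise is multiplicative Gaussian, `C * (1 + eps)` with
#' `eps ~ N(0, gamma^2)` i.i.d. per time point and `gamma = 1/SNR`; the SNR is
#' drawn once per curve from `U(snr_low, snr_high)`. `snr_low = snr_high = Inf`
#' disables noise.
#'
#' @param snr_low,snr_high Unitless SNR bounds (defaults 4 and 32).
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(snr_low = 4, snr_high = 32) {
  if (!is.numeric(snr_low) || !is.numeric(snr_high) || length(snr_low) != 1L ||
      length(snr_high) != 1L || is.na(snr_low) || is.na(snr_high) ||
      snr_low <= 0 || snr_low > snr_high) {
    stop("need 0 < snr_low <= snr_high", call. = FALSE)
  }
  structure(list(snr_low = snr_low, snr_high = snr_high), class = "noise_config")
}

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a child seed (< 2^31) from a base seed and a stream index.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %% 2147483629
}

#' Sample pharmacokinetic parameters from the prior
#'
#' @param prior A [prior_config()].
#' @param n Number of draws.
#' @param seed Integer seed; identical seeds give identical draws.
#' @return A data frame with columns `ktrans`, `kep`, `t0`, `lambda_weight`.
#' @export
sample_pk_params <- function(prior = prior_config(), n, seed = 1L) {
  if (!inherits(prior, "prior_config")) stop("`prior` must be a `prior_config`", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("`n` must be >= 1", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed, data.frame(
    ktrans = prior$ktrans_scale * stats::rbeta(n, prior$ktrans_shape[1], prior$ktrans_shape[2]),
    kep = prior$kep_scale * stats::rbeta(n, prior$kep_shape[1], prior$kep_shape[2]),
    t0 = stats::runif(n, 0, prior$t0_max),
    lambda_weight = stats::rbeta(n, prior$lambda_shape[1], prior$lambda_shape[2])
  ))
}

#' Add multiplicative Gaussian noise to a concentration curve
#'
#' `C_noisy(t) = max(0, C(t) * (1 + eps_t))` with `eps_t ~ N(0, gamma^2)` and
#' `gamma = 1/SNR`, SNR drawn once per curve from the configured range. The
#' rectifier keeps concentrations nonnegative.
#'
#' @param curve Numeric concentration curve.
#' @param noise A [noise_config()].
#' @param seed Integer seed.
#' @return The noisy, rectified curve.
#' @export
add_noise <- function(curve, noise = noise_config(), seed = 1L) {
  if (!is.numeric(curve) || !all(is.finite(curve))) {
    stop("`curve` must be a finite numeric vector", call. = FALSE)
  }
  if (!inherits(noise, "noise_config")) stop("`noise` must be a `noise_config`", call. = FALSE)
  with_seed(seed, {
    gamma <- if (is.infinite(noise$snr_low)) 0
             else 1 / stats::runif(1, noise$snr_low, noise$snr_high)
    pmax(0, curve * (1 + stats::rnorm(length(curve), 0, gamma)))
  })
}

#' Synthesize training pairs of noisy curves and their parameters
#'
#' Draws parameters from the prior, runs the fMRDI forward model and applies
#' multiplicative noise, producing the `(curve, parameters)` pairs the network
#' trains on. Deterministic for a fixed seed.
#'
#' @param prior A [prior_config()].
#' @param noise A [noise_config()], or `NULL` to disable noise.
#' @param grid A [time_grid()].
#' @param n Number of pairs.
#' @param seed Integer seed.
#' @param supersample Forward-model quadrature refinement (default 10).
#' @return A list with `curves` (`n x L` matrix, one curve per row) and
#'   `params` (data frame as from [sample_pk_params()]).
#' @export
synthesize_batch <- function(prior = prior_config(), noise = noise_config(),
                             grid = time_grid(), n, seed = 1L, supersample = 10L) {
  assert_grid(grid)
  params <- sample_pk_params(prior, n, seed = child_seed(seed, 1))
  n <- nrow(params)
  fine <- supersample_grid(grid, supersample)
  fast <- fmrdi_fast_basis()
  slow <- fmrdi_slow_basis()
  curves <- matrix(0, n, grid$n_points)
  noisy <- !is.null(noise)
  if (noisy && !inherits(noise, "noise_config")) {
    stop("`noise` must be a `noise_config` or NULL", call. = FALSE)
  }
  with_seed(child_seed(seed, 2), {
    for (i in seq_len(n)) {
      tsh <- fine$times - params$t0[i] * 60
      cp <- params$lambda_weight[i] * ldrw_values(tsh, fast) +
        (1 - params$lambda_weight[i]) * ldrw_values(tsh, slow)
      ct <- tissue_conv(cp, params$ktrans[i] / 60, params$kep[i] / 60, fine$dt)[fine$pick]
      if (noisy) {
        gamma <- if (is.infinite(noise$snr_low)) 0
                 else 1 / stats::runif(1, noise$snr_low, noise$snr_high)
        ct <- pmax(0, ct * (1 + stats::rnorm(length(ct), 0, gamma)))
      }
      curves[i, ] <- ct
    }
  })
  list(curves = curves, params = params)
}

#' Generate digital reference objects (DROs)
#'
#' DROs are synthetic Tofts curves with known ground truth, used to validate
#' fitting methods: `ktrans ~ U(0, 0.4)`, `kep ~ U(0, 2)` (1/min), no
#' dispersion weight and no arrival delay. They are generated like the
#' training curves but with a single reference AIF: the fast LDRW basis by
#' default (the training AIF family; a Parker `aif_spec` swaps in the
#' population AIF). Noise is multiplicative Gaussian at a fixed level
#' `gamma`. Truths are binned on a 10 x 10 grid of equal cells over the
#' sampling rectangle.
#'
#' @param n Number of DROs (default 100000).
#' @param noise_level The multiplicative noise standard deviation `gamma`
#'   (0 disables noise).
#' @param grid A [time_grid()].
#' @param seed Integer seed.
#' @param aif Reference [aif_spec()] (default: fast LDRW basis).
#' @param n_bins Bins per axis (default 10).
#' @param supersample Forward-model quadrature refinement.
#' @return An object of class `dro_set`: `curves` (`n x L`), `truths`
#'   (data frame `ktrans`, `kep`), `noise_level`, `bin_edges`, `grid`.
#' @export
generate_dros <- function(n = 100000L, noise_level = 0, grid = time_grid(),
                          seed = 1L, aif = aif_spec("ldrw", params = fmrdi_fast_basis()),
                          n_bins = 10L, supersample = 10L) {
  assert_grid(grid)
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (!is.numeric(noise_level) || length(noise_level) != 1L ||
      !is.finite(noise_level) || noise_level < 0) {
    stop("`noise_level` must be a single number >= 0", call. = FALSE)
  }
  n <- as.integer(n)
  fine <- supersample_grid(grid, supersample)
  cp <- eval_aif(aif, fine$times, dt_fine = fine$dt)  # shared: t0 = 0 for DROs
  curves <- matrix(0, n, grid$n_points)
  truths <- with_seed(child_seed(seed, 1), data.frame(
    ktrans = stats::runif(n, 0, 0.4),
    kep = stats::runif(n, 0, 2)
  ))
  with_seed(child_seed(seed, 2), {
    for (i in seq_len(n)) {
      ct <- tissue_conv(cp, truths$ktrans[i] / 60, truths$kep[i] / 60, fine$dt)[fine$pick]
      if (noise_level > 0) {
        ct <- pmax(0, ct * (1 + stats::rnorm(length(ct), 0, noise_level)))
      }
      curves[i, ] <- ct
    }
  })
  structure(list(curves = curves, truths = truths, noise_level = noise_level,
                 bin_edges = list(ktrans = seq(0, 0.4, length.out = n_bins + 1L),
                                  kep = seq(0, 2, length.out = n_bins + 1L)),
                 grid = grid),
            class = "dro_set")
}

#' @export
print.dro_set <- function(x, ...) {
  cat(sprintf("<dro_set> %d curves, %d time points, noise gamma = %g\n",
              nrow(x$curves), ncol(x$curves), x$noise_level))
  invisible(x)
}
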