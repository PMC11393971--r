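#' Arterial input function (AIF) families
#'
#' Tracer-kinetic analysis of DCE-MRI needs the plasma concentration feeding
#' the tissue, `Cp(t)`. Four families are provided:
#'
#' * **Parker**: the population AIF, a sum of two Gaussians plus a
#'   sigmoid-modulated exponential, with the published population constants.
#' * **LDRW**: the local-density-random-walk indicator-dilution curve used by
#'   MR dispersion imaging (MRDI), parameterized by a dispersion parameter
#'   `kappa` (1/s) and a mean transit time `mu` (s).
#' * **mMRDI transport**: a base AIF convolved with a vascular transport
#'   kernel `(1/lambda) * exp(-t/lambda)`.
#' * **fMRDI weighted sum**: `lambda * Cp_fast + (1 - lambda) * Cp_slow`,
#'   mixing a low-dispersion and a high-dispersion LDRW basis.
#'
#' @name aif
NULL

# ---- LDRW ------------------------------------------------------------------

#' LDRW dispersion AIF parameters
#'
#' @param kappa Dispersion parameter, 1/s, > 0.
#' @param mu Mean transit time, s, > 0.
#' @param alpha Area scale, concentration * s, > 0. The default `NULL` matches
#'   the curve's 0--400 s integral to the Parker population AIF's, so that
#'   Ktrans stays on a comparable scale across AIF choices.
#' @param t0_shift Arrival delay, s, >= 0.
#' @return An object of class `ldrw_params`.
#' @export
ldrw_params <- function(kappa = 0.3, mu = 10, alpha = NULL, t0_shift = 0) {
  if (is.null(alpha)) alpha <- ldrw_matched_alpha(kappa, mu)
  vals <- c(kappa = kappa, mu = mu, alpha = alpha, t0_shift = t0_shift)
  if (!all(is.finite(vals))) stop("LDRW parameters must be finite", call. = FALSE)
  if (kappa <= 0 || mu <= 0 || alpha <= 0) {
    stop("`kappa`, `mu` and `alpha` must be strictly positive", call. = FALSE)
  }
  if (t0_shift < 0) stop("`t0_shift` must be >= 0", call. = FALSE)
  structure(as.list(vals), class = "ldrw_params")
}

# Pointwise LDRW density at arbitrary times (seconds); zero for t <= t0_shift.
ldrw_values <- function(times, p) {
  s <- times - p$t0_shift
  out <- numeric(length(times))
  pos <- s > 0
  sp <- s[pos]
  out[pos] <- p$alpha * sqrt(p$kappa / (2 * pi * sp)) *
    exp(-p$kappa * (sp - p$mu)^2 / (2 * sp))
  out
}

# d/dt of the LDRW curve (needed for analytic bolus-arrival gradients).
ldrw_dvalues <- function(times, p) {
  s <- times - p$t0_shift
  out <- numeric(length(times))
  pos <- s > 0
  sp <- s[pos]
  v <- p$alpha * sqrt(p$kappa / (2 * pi * sp)) *
    exp(-p$kappa * (sp - p$mu)^2 / (2 * sp))
  out[pos] <- v * (-1 / (2 * sp) - (p$kappa / 2) * (1 - p$mu^2 / sp^2))
  out
}

#' Evaluate the LDRW dispersion AIF on a time grid
#'
#' `Cp(t) = alpha * sqrt(kappa / (2*pi*(t - t0))) *
#'   exp(-kappa * (t - t0 - mu)^2 / (2 * (t - t0)))` for `t > t0`, zero
#' otherwise.
#'
#' @param grid A [time_grid()].
#' @param p An [ldrw_params()] record.
#' @return Numeric vector of concentrations, one per grid time.
#' @export
evaluate_ldrw <- function(grid, p) {
  assert_grid(grid)
  if (!inherits(p, "ldrw_params")) stop("`p` must be an `ldrw_params` record", call. = FALSE)
  ldrw_values(grid$times, p)
}

# alpha that equates the LDRW 0-400 s integral with the Parker AIF's.
# Memoized: fitting loops call this with repeated (kappa, mu).
.fmrdi_cache <- new.env(parent = emptyenv())

ldrw_matched_alpha <- function(kappa, mu, window = 400, dt = 0.02) {
  if (!is.finite(kappa) || !is.finite(mu) || kappa <= 0 || mu <= 0) {
    stop("`kappa` and `mu` must be finite and strictly positive", call. = FALSE)
  }
  key <- sprintf("alpha_%.10g_%.10g", kappa, mu)
  hit <- .fmrdi_cache[[key]]
  if (!is.null(hit)) return(hit)
  ts <- seq(dt, window, by = dt)
  mass <- sum(sqrt(kappa / (2 * pi * ts)) * exp(-kappa * (ts - mu)^2 / (2 * ts))) * dt
  a <- parker_area(window) / mass
  assign(key, a, envir = .fmrdi_cache)
  a
}

# ---- Parker ----------------------------------------------------------------

#' Parker population AIF parameters
#'
#' The published population constants of the two-Gaussian + sigmoid-exponential
#' model, in minute-based units: Gaussian scales `a1`, `a2` (mmol.min/L),
#' centres `t1`, `t2` (min), widths `sigma1`, `sigma2` (min); exponential
#' amplitude `amp` (mmol/L) and decay `beta` (1/min); sigmoid steepness `s`
#' (1/min) and centre `tau` (min). All stored in one editable record.
#'
#' @param a1,a2,t1,t2,sigma1,sigma2,amp,beta,s,tau Model constants; defaults
#'   are the published population values.
#' @return An object of class `parker_params`.
#' @export
parker_params <- function(a1 = 0.809, a2 = 0.330, t1 = 0.17046, t2 = 0.365,
                          sigma1 = 0.0563, sigma2 = 0.132,
                          amp = 1.050, beta = 0.1685, s = 38.078, tau = 0.483) {
  vals <- c(a1 = a1, a2 = a2, t1 = t1, t2 = t2, sigma1 = sigma1,
            sigma2 = sigma2, amp = amp, beta = beta, s = s, tau = tau)
  if (!all(is.finite(vals))) stop("Parker parameters must be finite", call. = FALSE)
  if (sigma1 <= 0 || sigma2 <= 0 || s <= 0) {
    stop("Gaussian widths and sigmoid steepness must be strictly positive", call. = FALSE)
  }
  structure(as.list(vals), class = "parker_params")
}

# times in seconds; Parker constants are minute-based and converted here.
parker_values <- function(times, p = parker_params()) {
  tm <- times / 60
  out <- numeric(length(times))
  pos <- tm >= 0
  t <- tm[pos]
  out[pos] <- p$a1 / (p$sigma1 * sqrt(2 * pi)) * exp(-(t - p$t1)^2 / (2 * p$sigma1^2)) +
    p$a2 / (p$sigma2 * sqrt(2 * pi)) * exp(-(t - p$t2)^2 / (2 * p$sigma2^2)) +
    p$amp * exp(-p$beta * t) / (1 + exp(-p$s * (t - p$tau)))
  out
}

#' Evaluate the Parker population AIF on a time grid
#'
#' @param grid A [time_grid()].
#' @param p A [parker_params()] record.
#' @return Numeric vector of plasma concentrations (mmol/L).
#' @export
evaluate_parker <- function(grid, p = parker_params()) {
  assert_grid(grid)
  if (!inherits(p, "parker_params")) stop("`p` must be a `parker_params` record", call. = FALSE)
  parker_values(grid$times, p)
}

# Parker AIF time-integral over [0, window] seconds (mmol*s/L), memoized.
parker_area <- function(window = 400, dt = 0.005) {
  key <- sprintf("parker_area_%g", window)
  hit <- .fmrdi_cache[[key]]
  if (!is.null(hit)) return(hit)
  ts <- seq(0, window, by = dt)
  a <- sum(parker_values(ts)) * dt
  assign(key, a, envir = .fmrdi_cache)
  a
}

# ---- transport kernel (mMRDI) ---------------------------------------------

#' Apply a vascular transport kernel to an AIF curve
#'
#' Convolves a sampled input function with the unit-area causal kernel
#' `(1/lambda) * exp(-t/lambda)`. The kernel is discretized (normalized to
#' unit discrete mass, causally truncated) on a grid refined by `supersample`
#' before decimating back to the acquisition samples.
#'
#' @param base Numeric vector: the input function sampled on `grid`.
#' @param lambda_transport Dispersion coefficient, seconds, > 0.
#' @param grid The [time_grid()] that `base` lives on.
#' @param supersample Integer refinement factor for the kernel discretization
#'   (default 10).
#' @return Numeric vector of the dispersed curve, same length as `base`.
#' @export
apply_transport <- function(base, lambda_transport, grid, supersample = 10L) {
  assert_grid(grid)
  if (!is.numeric(base) || length(base) != grid$n_points || !all(is.finite(base))) {
    stop("`base` must be a finite numeric vector matching the grid length", call. = FALSE)
  }
  if (!is.numeric(lambda_transport) || length(lambda_transport) != 1L ||
      !is.finite(lambda_transport) || lambda_transport <= 0) {
    stop("`lambda_transport` must be a single positive number (seconds)", call. = FALSE)
  }
  fine <- supersample_grid(grid, supersample)
  xf <- if (supersample > 1L) {
    stats::approx(grid$times, base, xout = fine$times)$y
  } else {
    base
  }
  yf <- transport_filter(xf, lambda_transport, fine$dt)
  yf[fine$pick]
}

# Convolution with the unit-area transport kernel (1/lambda) e^{-t/lambda}:
# the same exponential-integrator recursion as the tissue convolution (exact
# for the piecewise-linear interpolant of x), scaled by 1/lambda. A constant
# input maps to itself in steady state, a vanishing lambda reduces to the
# identity, and the causally truncated output area never exceeds the input's.
transport_filter <- function(x, lambda, dt) {
  exp_conv_apply(x, exp_conv_coeffs(1 / lambda, dt)) / lambda
}

# ---- fMRDI weighted-sum AIF ------------------------------------------------

#' Default fast / slow LDRW bases of the fMRDI AIF
#'
#' The fast (low-dispersion) basis uses `kappa = 0.3` 1/s, `mu = 10` s; the
#' slow (high-dispersion) basis `kappa = 0.1` 1/s, `mu = 20` s. Both are
#' area-matched to the Parker AIF.
#'
#' @return An [ldrw_params()] record.
#' @export
fmrdi_fast_basis <- function() ldrw_params(kappa = 0.3, mu = 10)

#' @rdname fmrdi_fast_basis
#' @export
fmrdi_slow_basis <- function() ldrw_params(kappa = 0.1, mu = 20)

#' Evaluate the fMRDI weighted-sum AIF
#'
#' `Cp(t) = lambda * Cp_fast(t - t0) + (1 - lambda) * Cp_slow(t - t0)`. The
#' dispersion weight `lambda` is near 1 for fast, low-dispersion uptake
#' (typical of csPCa) and near 0 for slow, high-dispersion uptake.
#'
#' @param grid A [time_grid()].
#' @param lambda_weight Dispersion weight in `[0, 1]`.
#' @param t0 Arrival delay in seconds (default 0).
#' @param fast,slow The two [ldrw_params()] bases.
#' @return Numeric vector of plasma concentrations.
#' @export
evaluate_fmrdi_aif <- function(grid, lambda_weight, t0 = 0,
                               fast = fmrdi_fast_basis(), slow = fmrdi_slow_basis()) {
  assert_grid(grid)
  check_unit_interval(lambda_weight, "lambda_weight")
  fmrdi_aif_values(grid$times - t0, lambda_weight, fast, slow)
}

fmrdi_aif_values <- function(times, lambda_weight, fast = fmrdi_fast_basis(),
                             slow = fmrdi_slow_basis()) {
  lambda_weight * ldrw_values(times, fast) +
    (1 - lambda_weight) * ldrw_values(times, slow)
}

check_unit_interval <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single number in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

# ---- tagged AIF specification ---------------------------------------------

#' Tagged AIF specification
#'
#' A serializable description of a plasma input function, used by the forward
#' models and the config files.
#'
#' @param kind One of `"parker"`, `"ldrw"`, `"mmrdi_transport"`,
#'   `"fmrdi_weighted"`.
#' @param params Parameter record for `"parker"` / `"ldrw"` kinds.
#' @param base An `aif_spec` the transport kernel is applied to
#'   (`"mmrdi_transport"` only; default Parker).
#' @param lambda_transport Transport dispersion coefficient, s, > 0
#'   (`"mmrdi_transport"` only).
#' @param fast,slow LDRW bases (`"fmrdi_weighted"` only).
#' @param lambda_weight Dispersion weight in `[0, 1]` (`"fmrdi_weighted"` only).
#' @return An object of class `aif_spec`.
#' @export
aif_spec <- function(kind = c("parker", "ldrw", "mmrdi_transport", "fmrdi_weighted"),
                     params = NULL, base = NULL, lambda_transport = NULL,
                     fast = fmrdi_fast_basis(), slow = fmrdi_slow_basis(),
                     lambda_weight = NULL) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    parker = {
      if (is.null(params)) params <- parker_params()
      if (!inherits(params, "parker_params")) stop("`params` must be `parker_params`", call. = FALSE)
      list(kind = kind, params = params)
    },
    ldrw = {
      if (is.null(params)) params <- fmrdi_fast_basis()
      if (!inherits(params, "ldrw_params")) stop("`params` must be `ldrw_params`", call. = FALSE)
      list(kind = kind, params = params)
    },
    mmrdi_transport = {
      if (is.null(base)) base <- aif_spec("parker")
      if (!inherits(base, "aif_spec")) stop("`base` must be an `aif_spec`", call. = FALSE)
      if (is.null(lambda_transport) || !is.numeric(lambda_transport) ||
          length(lambda_transport) != 1L || !is.finite(lambda_transport) ||
          lambda_transport <= 0) {
        stop("`lambda_transport` must be a single positive number (seconds)", call. = FALSE)
      }
      list(kind = kind, base = base, lambda_transport = as.numeric(lambda_transport))
    },
    fmrdi_weighted = {
      if (is.null(lambda_weight)) lambda_weight <- 0.5
      check_unit_interval(lambda_weight, "lambda_weight")
      if (!inherits(fast, "ldrw_params") || !inherits(slow, "ldrw_params")) {
        stop("`fast` and `slow` must be `ldrw_params` records", call. = FALSE)
      }
      list(kind = kind, fast = fast, slow = slow, lambda_weight = lambda_weight)
    }
  )
  structure(spec, class = "aif_spec")
}

#' Evaluate a tagged AIF specification at arbitrary times
#'
#' @param spec An [aif_spec()].
#' @param times Numeric vector of times in seconds, or a [time_grid()].
#' @param dt_fine Sampling interval of `times` (needed only for the transport
#'   kernel of `"mmrdi_transport"`; inferred from `times` when uniform).
#' @return Numeric vector of plasma concentrations.
#' @export
eval_aif <- function(spec, times, dt_fine = NULL) {
  if (!inherits(spec, "aif_spec")) stop("`spec` must be an `aif_spec`", call. = FALSE)
  if (is_time_grid(times)) {
    if (is.null(dt_fine)) dt_fine <- times$dt
    times <- times$times
  }
  switch(spec$kind,
    parker = parker_values(times),
    ldrw = ldrw_values(times, spec$params),
    fmrdi_weighted = fmrdi_aif_values(times, spec$lambda_weight, spec$fast, spec$slow),
    mmrdi_transport = {
      if (is.null(dt_fine)) {
        dts <- diff(times)
        if (length(dts) == 0L || max(abs(dts - dts[1])) > 1e-9 * dts[1]) {
          stop("`mmrdi_transport` needs uniformly spaced `times` (or `dt_fine`)", call. = FALSE)
        }
        dt_fine <- dts[1]
      }
      base_vals <- eval_aif(spec$base, times, dt_fine)
      transport_filter(base_vals, spec$lambda_transport, dt_fine)
    }
  )
}

# d/dt of an AIF spec at arbitrary times (analytic where available); used for
# bolus-arrival-time gradients. Only the kinds that appear inside gradient-based
# fitting need this.
eval_aif_deriv <- function(spec, times) {
  switch(spec$kind,
    ldrw = ldrw_dvalues(times, spec$params),
    fmrdi_weighted = spec$lambda_weight * ldrw_dvalues(times, spec$fast) +
      (1 - spec$lambda_weight) * ldrw_dvalues(times, spec$slow),
    stop(sprintf("no analytic time derivative for AIF kind '%s'", spec$kind), call. = FALSE)
  )
}

#' Serialize / deserialize an AIF specification
#'
#' `aif_spec_to_list()` produces a plain list round-trippable through JSON or
#' YAML (`aif: {kind: fmrdi_weighted, lambda_weight: 0.5, ...}`);
#' `aif_spec_from_list()` rebuilds the `aif_spec`.
#'
#' @param spec An [aif_spec()].
#' @param x A plain list as produced by `aif_spec_to_list()`.
#' @return A list, or an `aif_spec`.
#' @export
aif_spec_to_list <- function(spec) {
  if (!inherits(spec, "aif_spec")) stop("`spec` must be an `aif_spec`", call. = FALSE)
  out <- unclass(spec)
  if (!is.null(out$params)) out$params <- unclass(out$params)
  if (!is.null(out$fast)) out$fast <- unclass(out$fast)
  if (!is.null(out$slow)) out$slow <- unclass(out$slow)
  if (!is.null(out$base)) out$base <- aif_spec_to_list(out$base)
  out
}

#' @rdname aif_spec_to_list
#' @export
aif_spec_from_list <- function(x) {
  kind <- x$kind
  switch(kind,
    parker = aif_spec("parker", params = do.call(parker_params, x$params %||% list())),
    ldrw = aif_spec("ldrw", params = do.call(ldrw_params, x$params %||% list())),
    mmrdi_transport = aif_spec("mmrdi_transport",
                               base = aif_spec_from_list(x$base),
                               lambda_transport = x$lambda_transport),
    fmrdi_weighted = aif_spec("fmrdi_weighted",
                              fast = do.call(ldrw_params, x$fast %||% list()),
                              slow = do.call(ldrw_params, x$slow %||% list()),
                              lambda_weight = x$lambda_weight),
    stop(sprintf("unknown AIF kind '%s'", kind), call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
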