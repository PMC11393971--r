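#' Pharmacokinetic parameter record
#'
#' The estimand of the fMRDI model: the volume-transfer constant `ktrans`
#' (1/min), the washout rate constant `kep` (1/min), the bolus arrival time
#' `t0` (min) and the intravascular dispersion weight `lambda_weight` in
#' `[0, 1]` (near 1 for fast, low-dispersion uptake; near 0 for slow,
#' high-dispersion uptake).
#'
#' @param ktrans Volume-transfer constant, 1/min, >= 0.
#' @param kep Rate constant, 1/min, >= 0.
#' @param t0 Bolus arrival time, min, >= 0.
#' @param lambda_weight Dispersion weight, unitless, in `[0, 1]`.
#' @return An object of class `pk_params`.
#' @export
pk_params <- function(ktrans, kep, t0 = 0, lambda_weight = 0.5) {
  vals <- c(ktrans = ktrans, kep = kep, t0 = t0, lambda_weight = lambda_weight)
  if (!all(is.finite(vals))) stop("PK parameters must be finite", call. = FALSE)
  if (ktrans < 0 || kep < 0 || t0 < 0) {
    stop("`ktrans`, `kep` and `t0` must be >= 0", call. = FALSE)
  }
  check_unit_interval(lambda_weight, "lambda_weight")
  structure(as.list(vals), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("<pk_params> Ktrans = %.4g /min, kep = %.4g /min, t0 = %.4g min, lambda = %.4g\n",
              x$ktrans, x$kep, x$t0, x$lambda_weight))
  invisible(x)
}

pk_as_vector <- function(p) {
  c(ktrans = p$ktrans, kep = p$kep, t0 = p$t0, lambda_weight = p$lambda_weight)
}

pk_from_vector <- function(v) {
  pk_params(ktrans = v[[1]], kep = v[[2]], t0 = v[[3]], lambda_weight = v[[4]])
}

# Exponential-integrator quadrature for the tissue convolution
# Ct(t) = Ktrans * int_0^t Cp(tau) exp(-kep (t - tau)) dtau: the convolution
# of the piecewise-linear interpolant of the sampled AIF with the exponential
# impulse response is computed exactly by the recursion
#   y_i = a y_{i-1} + c1 cp_i + c0 cp_{i-1},  a = exp(-kep dt),
# which is second-order accurate in dt and exact for kep = 0 (running
# trapezoid integral). The coefficients and their kep-derivatives (needed for
# analytic gradients) are computed stably via expm1, with a series fallback
# for kep*dt near 0.
exp_conv_coeffs <- function(k, dt) {
  kdt <- k * dt
  a <- exp(-kdt)
  if (kdt < 1e-4) {
    c1 <- dt / 2 - kdt * dt / 6 + kdt^2 * dt / 24
    c0 <- dt / 2 - kdt * dt / 3 + kdt^2 * dt / 8
    dc1 <- -dt^2 / 6 + k * dt^3 / 12
    dc0 <- -dt^2 / 3 + k * dt^3 / 4
  } else {
    one_m_a <- -expm1(-kdt)
    c1 <- (kdt + expm1(-kdt)) / (k^2 * dt)
    c0 <- one_m_a / k - c1
    dc1 <- (-kdt * (1 + a) + 2 * one_m_a) / (k^3 * dt)
    dI0 <- (kdt * a - one_m_a) / k^2
    dc0 <- dI0 - dc1
  }
  list(a = a, c0 = c0, c1 = c1, da = -dt * a, dc0 = dc0, dc1 = dc1)
}

lag1 <- function(x) c(0, x[-length(x)])

# y_1 = 0 (nothing integrated yet); y_i = a y_{i-1} + c1 x_i + c0 x_{i-1}
exp_conv_apply <- function(x, co) {
  z <- co$c1 * x + co$c0 * lag1(x)
  z[1] <- 0
  as.numeric(stats::filter(z, co$a, method = "recursive"))
}

# Rates here are per second.
tissue_conv <- function(cp_fine, ktrans_s, kep_s, dt_fine) {
  ktrans_s * exp_conv_apply(cp_fine, exp_conv_coeffs(kep_s, dt_fine))
}

#' Tofts forward model
#'
#' Tissue concentration as the causal convolution of the (shifted) arterial
#' input function with the impulse response `Ktrans * exp(-kep * t)`:
#' `Ct(t) = integral_0^t Cp(tau - t0) * Ktrans * exp(-kep * (t - tau)) dtau`.
#' The quadrature runs on a grid refined by `supersample` (exponential-
#' integrator scheme, exact for a piecewise-linear AIF) and is decimated back
#' to the acquisition samples. Rates are stored in
#' 1/min and converted to 1/s internally; `t0` is applied once, inside the
#' AIF shift.
#'
#' @param pk A [pk_params()] record (`lambda_weight` is ignored unless
#'   `aif$kind == "fmrdi_weighted"`, where it overrides the weight stored in the AIF specification).
#' @param aif An [aif_spec()].
#' @param grid A [time_grid()].
#' @param supersample Quadrature refinement factor (default 10).
#' @return Numeric vector of tissue concentrations, one per grid time.
#' @export
tofts_forward <- function(pk, aif, grid, supersample = 10L) {
  assert_grid(grid)
  if (!inherits(pk, "pk_params")) stop("`pk` must be a `pk_params` record", call. = FALSE)
  if (!inherits(aif, "aif_spec")) stop("`aif` must be an `aif_spec`", call. = FALSE)
  if (aif$kind == "fmrdi_weighted") {
    aif$lambda_weight <- pk$lambda_weight
  }
  fine <- supersample_grid(grid, supersample)
  cp <- eval_aif(aif, fine$times - pk$t0 * 60, dt_fine = fine$dt)
  ct <- tissue_conv(cp, pk$ktrans / 60, pk$kep / 60, fine$dt)
  ct[fine$pick]
}

#' fMRDI forward model
#'
#' The fast MR dispersion imaging model: the Tofts convolution driven by the
#' weighted-sum AIF `lambda * Cp_fast + (1 - lambda) * Cp_slow`. Equivalent to
#' [tofts_forward()] with an `"fmrdi_weighted"` AIF; affine in
#' `lambda_weight`.
#'
#' @inheritParams tofts_forward
#' @param fast,slow The LDRW bases of the weighted-sum AIF.
#' @return Numeric vector of tissue concentrations.
#' @examples
#' g <- time_grid()
#' ct <- fmrdi_forward(pk_params(0.25, 1.0, 0, 0.5), g)
#' @export
fmrdi_forward <- function(pk, grid, supersample = 10L,
                          fast = fmrdi_fast_basis(), slow = fmrdi_slow_basis()) {
  tofts_forward(pk, aif_spec("fmrdi_weighted", fast = fast, slow = slow,
                             lambda_weight = pk$lambda_weight),
                grid, supersample = supersample)
}

# fMRDI forward model with the analytic Jacobian wrt (ktrans, kep, t0, lambda),
# in the reported units (1/min, 1/min, min, unitless). Used by the gradient
# refinement rule and the trust-region fitter.
fmrdi_forward_jac <- function(pk, grid, supersample = 10L,
                              fast = fmrdi_fast_basis(), slow = fmrdi_slow_basis()) {
  fine <- supersample_grid(grid, supersample)
  tsh <- fine$times - pk$t0 * 60
  cf <- ldrw_values(tsh, fast)
  cs <- ldrw_values(tsh, slow)
  lam <- pk$lambda_weight
  cp <- lam * cf + (1 - lam) * cs
  dcp <- lam * ldrw_dvalues(tsh, fast) + (1 - lam) * ldrw_dvalues(tsh, slow)

  kt_s <- pk$ktrans / 60
  kep_s <- pk$kep / 60
  co <- exp_conv_coeffs(kep_s, fine$dt)

  Af <- exp_conv_apply(cf, co)
  As <- exp_conv_apply(cs, co)
  A <- lam * Af + (1 - lam) * As          # conv(cp, exp)
  # dA/dkep: differentiate the recursion y_i = a y_{i-1} + c1 cp_i + c0 cp_{i-1}
  u <- co$da * lag1(A) + co$dc1 * cp + co$dc0 * lag1(cp)
  u[1] <- 0
  Ak <- as.numeric(stats::filter(u, co$a, method = "recursive"))
  D <- exp_conv_apply(dcp, co)            # conv(cp', exp)

  values <- kt_s * A
  jac <- cbind(
    ktrans = A / 60,
    kep = kt_s * Ak / 60,
    t0 = -kt_s * D * 60,
    lambda_weight = kt_s * (Af - As)
  )
  list(values = values[fine$pick], jac = jac[fine$pick, , drop = FALSE])
}

#' Convert a T1 time series to contrast-agent concentration
#'
#' The contrast agent shortens T1: `1/T1(t) = 1/T10 + r1 * C(t)`, so
#' `C(t) = (1/T1(t) - 1/T10) / r1`. Negative enhancement (T1 above baseline,
#' e.g. from noise) is clamped to zero; the number of clamped samples is
#' attached as attribute `n_clamped` and reported in a warning.
#'
#' @param t1_series Per-frame T1 values, seconds, all > 0.
#' @param t10 Precontrast T1, seconds, > 0.
#' @param r1 Contrast-agent relaxivity, L/(mmol*s); default 4.5, the usual
#'   in vitro value.
#' @return Numeric vector of concentrations (mmol/L), with attribute
#'   `n_clamped`.
#' @export
concentration_from_t1 <- function(t1_series, t10, r1 = 4.5) {
  if (!is.numeric(t1_series) || !all(is.finite(t1_series)) || any(t1_series <= 0)) {
    stop("all T1 values must be finite and > 0", call. = FALSE)
  }
  if (!is.numeric(t10) || length(t10) != 1L || !is.finite(t10) || t10 <= 0) {
    stop("`t10` must be a single positive number (seconds)", call. = FALSE)
  }
  if (!is.numeric(r1) || length(r1) != 1L || !is.finite(r1) || r1 <= 0) {
    stop("`r1` must be a single positive number", call. = FALSE)
  }
  ct <- (1 / t1_series - 1 / t10) / r1
  n_clamped <- sum(ct < 0)
  if (n_clamped > 0) {
    warning(sprintf("%d sample(s) with negative enhancement clamped to zero", n_clamped),
            call. = FALSE)
    ct[ct < 0] <- 0
  }
  attr(ct, "n_clamped") <- n_clamped
  ct
}

#' Zero the precontrast frames of a concentration curve
#'
#' Dynamic frames acquired before bolus arrival carry only noise; they are
#' located by the largest frame-to-frame rise within the first `search_frames`
#' frames and set to zero for ease of optimization. The frame before the
#' steepest rise is taken as the last precontrast frame; ties break to the
#' earliest frame.
#'
#' @param curve Numeric concentration curve (length >= 2).
#' @param search_frames Number of leading frames searched for the steepest
#'   rise (default 15).
#' @return A list with `curve` (leading frames zeroed) and
#'   `last_precontrast`, the 1-based index of the last zeroed frame.
#' @export
zero_precontrast <- function(curve, search_frames = 15L) {
  if (!is.numeric(curve) || length(curve) < 2L || !all(is.finite(curve))) {
    stop("`curve` must be a finite numeric vector of length >= 2", call. = FALSE)
  }
  search_frames <- min(as.integer(search_frames), length(curve))
  if (search_frames < 2L) stop("`search_frames` must be >= 2", call. = FALSE)
  d <- diff(curve[seq_len(search_frames)])
  k <- which.max(d)  # steepest rise arrives at frame k + 1; ties -> earliest
  out <- curve
  out[seq_len(k)] <- 0
  list(curve = out, last_precontrast = k)
}
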