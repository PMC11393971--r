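#' Curve-fitting configuration
#'
#' Controls both fitting routes: the gradient refinement rule
#' (`P <- P - gamma * d||f(P) - Ct||^2/dP`, projected to bounds and guarded so
#' the residual never increases) and bounded trust-region nonlinear least
#' squares (Levenberg-Marquardt with box constraints). The refinement budget
#' defaults to `T = 20` iterations; fitting from scratch defaults to 240.
#'
#' @param method `"trust_region"` or `"gradient_refine"`.
#' @param max_iterations Iteration budget; `NULL` picks 20 for
#'   `gradient_refine` / refinement and 240 for from-scratch trust-region
#'   fits.
#' @param step_size Gradient-refinement learning rate `gamma` (default 0.01).
#' @param step_tolerance,function_tolerance,min_gradient_change Trust-region
#'   stopping tolerances (defaults 1e-2, 1e-3, 0.1).
#' @param restarts Random initializations for from-scratch fits (default 10).
#' @param convergence_window,convergence_rtol An iterative run is declared
#'   converged when the relative loss reduction stays below
#'   `convergence_rtol` (default 0.5%) for `convergence_window` (default 5)
#'   consecutive iterations.
#' @param bounds Named list of `c(lower, upper)` per parameter; defaults
#'   ktrans `[0, 2]` 1/min, kep `[0, 5]` 1/min, t0 `[0, 0.5]` min,
#'   lambda_weight `[0, 1]`, plus ranges for the dispersion parameters of the
#'   MRDI / mMRDI families.
#' @param seed Integer seed for the random restarts.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(method = c("trust_region", "gradient_refine"),
                       max_iterations = NULL, step_size = 0.01,
                       step_tolerance = 1e-2, function_tolerance = 1e-3,
                       min_gradient_change = 0.1, restarts = 10L,
                       convergence_window = 5L, convergence_rtol = 0.005,
                       bounds = NULL, seed = 1L) {
  method <- match.arg(method)
  if (step_size < 0 || step_tolerance <= 0 || function_tolerance <= 0 ||
      min_gradient_change <= 0 || convergence_rtol <= 0) {
    stop("tolerances must be positive and `step_size` >= 0", call. = FALSE)
  }
  if (restarts < 1) stop("`restarts` must be >= 1", call. = FALSE)
  default_bounds <- list(
    ktrans = c(0, 2), kep = c(0, 5), t0 = c(0, 0.5), lambda_weight = c(0, 1),
    lambda_transport = c(0.5, 60), kappa = c(0.02, 1), mu = c(2, 40)
  )
  if (!is.null(bounds)) default_bounds[names(bounds)] <- bounds
  for (nm in names(default_bounds)) {
    b <- default_bounds[[nm]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1] > b[2]) {
      stop(sprintf("bounds for `%s` must be an ordered pair", nm), call. = FALSE)
    }
  }
  structure(list(method = method, max_iterations = max_iterations,
                 step_size = step_size, step_tolerance = step_tolerance,
                 function_tolerance = function_tolerance,
                 min_gradient_change = min_gradient_change,
                 restarts = as.integer(restarts),
                 convergence_window = as.integer(convergence_window),
                 convergence_rtol = convergence_rtol,
                 bounds = default_bounds, seed = as.integer(seed)),
            class = "fit_config")
}

fit_result <- function(params, residual, iterations_used, converged, init,
                       model_kind) {
  structure(list(params = params, residual = residual,
                 iterations_used = iterations_used, converged = converged,
                 init = init, model_kind = model_kind),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: %s | residual %.5g, %d iteration(s), %s (init: %s)\n",
              x$model_kind,
              paste(sprintf("%s=%.4g", names(x$params), x$params), collapse = ", "),
              x$residual, x$iterations_used,
              if (x$converged) "converged" else "not converged", x$init))
  invisible(x)
}

# ---- model-kind registry ---------------------------------------------------

# Free parameter names per PK model family.
kind_free_params <- function(model_kind, fixed = NULL) {
  all <- switch(model_kind,
    tofts_parker = c("ktrans", "kep", "t0"),
    fmrdi = c("ktrans", "kep", "t0", "lambda_weight"),
    mmrdi = c("ktrans", "kep", "t0", "lambda_transport"),
    mrdi = c("ktrans", "kep", "t0", "kappa", "mu"),
    stop(sprintf("unknown model kind '%s'", model_kind), call. = FALSE)
  )
  setdiff(all, names(fixed))
}

# Forward model for a named parameter vector of the given family.
# `mmrdi_base` selects the population AIF the mMRDI transport kernel is
# applied to (Parker by default).
kind_forward <- function(theta, model_kind, grid, supersample = 10L,
                         mmrdi_base = NULL) {
  pk_of <- function() pk_params(theta[["ktrans"]], theta[["kep"]], theta[["t0"]],
                                theta[["lambda_weight"]] %||% 0)
  switch(model_kind,
    tofts_parker = tofts_forward(
      pk_params(theta[["ktrans"]], theta[["kep"]], theta[["t0"]]),
      aif_spec("parker"), grid, supersample),
    fmrdi = fmrdi_forward(pk_of(), grid, supersample),
    mmrdi = tofts_forward(
      pk_params(theta[["ktrans"]], theta[["kep"]], theta[["t0"]]),
      aif_spec("mmrdi_transport", base = mmrdi_base,
               lambda_transport = theta[["lambda_transport"]]),
      grid, supersample),
    mrdi = tofts_forward(
      pk_params(theta[["ktrans"]], theta[["kep"]], theta[["t0"]]),
      aif_spec("ldrw", params = ldrw_params(kappa = theta[["kappa"]], mu = theta[["mu"]])),
      grid, supersample)
  )
}

# Gradient of the squared residual wrt the free parameters: analytic via the
# fMRDI Jacobian where available, central finite differences otherwise.
residual_gradient <- function(theta, free, ct, model_kind, grid, supersample = 10L,
                              mmrdi_base = NULL) {
  if (model_kind == "fmrdi") {
    fj <- fmrdi_forward_jac(pk_params(theta[["ktrans"]], theta[["kep"]],
                                      theta[["t0"]], theta[["lambda_weight"]]),
                            grid, supersample)
    r <- fj$values - ct
    return(list(grad = 2 * drop(crossprod(fj$jac[, free, drop = FALSE], r)),
                residual = sum(r * r)))
  }
  f0 <- kind_forward(theta, model_kind, grid, supersample, mmrdi_base)
  r <- f0 - ct
  grad <- numeric(length(free))
  names(grad) <- free
  for (nm in free) {
    h <- max(1e-6, 1e-4 * abs(theta[[nm]]))
    tp <- theta; tp[[nm]] <- theta[[nm]] + h
    tm <- theta; tm [[nm]] <- theta[[nm]] - h
    jcol <- (kind_forward(tp, model_kind, grid, supersample, mmrdi_base) -
               kind_forward(tm, model_kind, grid, supersample, mmrdi_base)) / (2 * h)
    grad[nm] <- 2 * sum(r * jcol)
  }
  list(grad = grad, residual = sum(r * r))
}

clip_to_bounds <- function(theta, bounds) {
  for (nm in names(theta)) {
    b <- bounds[[nm]]
    if (!is.null(b)) theta[[nm]] <- min(max(theta[[nm]], b[1]), b[2])
  }
  theta
}

#' Gradient refinement of a parameter estimate
#'
#' Iterative refinement of an initial estimate by projected gradient descent
#' on the squared fitting error `||f(P) - Ct||^2` with a fixed step size
#' `gamma`. Each step is clipped to the parameter bounds; a step that would
#' increase the residual is retried with a halved step (guarded descent), so
#' the returned residual never exceeds the initial one.
#'
#' @param p0 Initial estimate: a [pk_params()] (fMRDI) or a named numeric
#'   vector of the family's parameters.
#' @param ct Observed concentration curve.
#' @param grid A [time_grid()].
#' @param cfg A [fit_config()]; `step_size` and `max_iterations` (default 20)
#'   control the iteration.
#' @param model_kind PK model family (default `"fmrdi"`).
#' @param fixed Named list of parameters to hold fixed (e.g.
#'   `list(t0 = 0, lambda_weight = 0)` for plain-Tofts refinement).
#' @param supersample Forward-model quadrature refinement.
#' @param mmrdi_base Population-AIF [aif_spec()] for the `"mmrdi"` family
#'   (default Parker).
#' @return A [fit_result()] with the refined parameters, final squared
#'   residual, iteration count and convergence flag.
#' @export
refine <- function(p0, ct, grid = time_grid(), cfg = fit_config("gradient_refine"),
                   model_kind = "fmrdi", fixed = NULL, supersample = 10L,
                   mmrdi_base = NULL) {
  assert_grid(grid)
  theta <- if (inherits(p0, "pk_params")) pk_as_vector(p0) else p0
  if (is.null(names(theta))) stop("`p0` must be named", call. = FALSE)
  theta <- clip_to_bounds(theta, cfg$bounds)
  free <- kind_free_params(model_kind, fixed)
  for (nm in names(fixed)) theta[[nm]] <- fixed[[nm]]
  max_it <- cfg$max_iterations %||% 20L
  gamma <- cfg$step_size

  gr <- residual_gradient(theta, free, ct, model_kind, grid, supersample, mmrdi_base)
  if (!is.finite(gr$residual)) stop("non-finite residual at the initial estimate", call. = FALSE)
  loss_hist <- gr$residual
  it_used <- 0L
  if (gamma > 0 && max_it > 0) {
    for (it in seq_len(max_it)) {
      step <- gamma
      improved <- FALSE
      for (half in 1:25) {
        cand <- theta
        cand[free] <- theta[free] - step * gr$grad
        cand <- clip_to_bounds(cand, cfg$bounds)
        f <- kind_forward(cand, model_kind, grid, supersample, mmrdi_base)
        res <- sum((f - ct)^2)
        if (is.finite(res) && res <= gr$residual) {
          improved <- TRUE
          break
        }
        step <- step / 2
      }
      it_used <- it
      if (!improved) break
      theta <- cand
      gr <- residual_gradient(theta, free, ct, model_kind, grid, supersample, mmrdi_base)
      loss_hist <- c(loss_hist, gr$residual)
      if (check_convergence(loss_hist, window = cfg$convergence_window,
                            rtol = cfg$convergence_rtol)) break
    }
  }
  fit_result(theta, gr$residual, it_used,
             check_convergence(loss_hist, cfg$convergence_window, cfg$convergence_rtol),
             init = "given", model_kind = model_kind)
}

#' Multi-restart bounded nonlinear least squares
#'
#' Fits a PK model family to a concentration curve by bounded
#' Levenberg-Marquardt minimization of the squared residual, repeated from
#' `cfg$restarts` random initializations drawn uniformly within the parameter
#' bounds; the restart with the lowest residual wins. This mirrors the
#' standard practice of repeated NLLS with random initializations to escape
#' poor local minima.
#'
#' @param ct Observed concentration curve.
#' @param model_kind One of `"tofts_parker"`, `"mrdi"`, `"mmrdi"`, `"fmrdi"`.
#' @param grid A [time_grid()].
#' @param cfg A [fit_config()].
#' @param fixed Named list of parameters held fixed.
#' @param init Optional named start (used for the first restart).
#' @param supersample Forward-model quadrature refinement.
#' @param mmrdi_base Population-AIF [aif_spec()] for the `"mmrdi"` family
#'   (default Parker).
#' @return A [fit_result()]; `init` records which restart won.
#' @export
nlls_fit <- function(ct, model_kind = "fmrdi", grid = time_grid(),
                     cfg = fit_config(), fixed = NULL, init = NULL,
                     supersample = 10L, mmrdi_base = NULL) {
  assert_grid(grid)
  if (length(ct) != grid$n_points) stop("curve length must match the grid", call. = FALSE)
  free <- kind_free_params(model_kind, fixed)
  full <- c(kind_free_params(model_kind), names(fixed))
  full <- unique(full)
  lower <- vapply(free, function(nm) cfg$bounds[[nm]][1], 0)
  upper <- vapply(free, function(nm) cfg$bounds[[nm]][2], 0)
  max_it <- cfg$max_iterations %||% 240L

  make_theta <- function(x) {
    theta <- numeric(0)
    theta[free] <- x
    for (nm in names(fixed)) theta[[nm]] <- fixed[[nm]]
    theta
  }
  resid_fn <- function(x) {
    kind_forward(make_theta(x), model_kind, grid, supersample, mmrdi_base) - ct
  }
  jac_fn <- if (model_kind == "fmrdi") {
    function(x) {
      theta <- make_theta(x)
      fmrdi_forward_jac(pk_params(theta[["ktrans"]], theta[["kep"]],
                                  theta[["t0"]], theta[["lambda_weight"]]),
                        grid, supersample)$jac[, free, drop = FALSE]
    }
  } else NULL

  starts <- with_seed(cfg$seed, {
    lapply(seq_len(cfg$restarts), function(i) stats::runif(length(free), lower, upper))
  })
  if (!is.null(init)) {
    init <- clip_to_bounds(init, cfg$bounds)
    starts[[1]] <- unname(init[free])
  }

  best <- NULL
  ctrl <- minpack.lm::nls.lm.control(
    ftol = cfg$function_tolerance, ptol = cfg$step_tolerance,
    gtol = cfg$min_gradient_change, maxiter = min(max_it, 1024L))
  for (i in seq_along(starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[[i]], lower = lower, upper = upper,
                         fn = resid_fn, jac = jac_fn, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    res <- sum(fit$fvec^2)
    if (!is.finite(res)) next
    cand <- list(theta = make_theta(fit$par), residual = res,
                 iterations = fit$niter, converged = fit$info %in% 1:4,
                 which = i)
    if (is.null(best) || res < best$residual) best <- cand
  }
  if (is.null(best)) {
    theta0 <- make_theta(starts[[1]])
    r0 <- sum(resid_fn(starts[[1]])^2)
    return(fit_result(theta0, r0, 0L, FALSE,
                      init = "restart 1 (all restarts failed)", model_kind = model_kind))
  }
  fit_result(best$theta, best$residual, best$iterations,
             best$converged,
             init = if (!is.null(init) && best$which == 1L) "given"
                    else sprintf("restart %d", best$which),
             model_kind = model_kind)
}

#' Two-stage fit: neural-network initialization plus refinement
#'
#' The coarse estimate from the network initializes a short refinement (the
#' default trust-region route runs bounded Levenberg-Marquardt for `T = 20`
#' iterations from the network estimate; `"gradient_refine"` applies the
#' fixed-step gradient rule instead). The result is guarded: if refinement
#' fails to improve on the network estimate, the network estimate is
#' returned, so the two-stage residual never exceeds the network-only
#' residual.
#'
#' @param model A trained `fmrdi_nn`.
#' @param ct Observed concentration curve (vector).
#' @param grid A [time_grid()].
#' @param cfg A [fit_config()]; its `method` selects the refinement route and
#'   `max_iterations` (default 20) the budget.
#' @param model_kind PK model family for the refinement (default `"fmrdi"`).
#' @param fixed Named list of parameters held fixed during refinement.
#' @param supersample Forward-model quadrature refinement.
#' @return A [fit_result()] with `init = "nn"`.
#' @export
two_stage_fit <- function(model, ct, grid = time_grid(), cfg = fit_config(),
                          model_kind = "fmrdi", fixed = NULL, supersample = 10L) {
  assert_grid(grid)
  p0 <- drop(predict_pk(model, ct))
  theta0 <- clip_to_bounds(p0, cfg$bounds)
  free <- kind_free_params(model_kind, fixed)
  for (nm in names(fixed)) theta0[[nm]] <- fixed[[nm]]
  theta0 <- theta0[unique(c(free, names(fixed)))]
  r0 <- sum((kind_forward(theta0, model_kind, grid, supersample) - ct)^2)
  max_it <- cfg$max_iterations %||% 20L

  if (cfg$method == "gradient_refine") {
    cfg$max_iterations <- max_it
    out <- refine(theta0, ct, grid, cfg, model_kind = model_kind, fixed = fixed,
                  supersample = supersample)
  } else {
    cfg1 <- cfg
    cfg1$restarts <- 1L
    cfg1$max_iterations <- max_it
    out <- nlls_fit(ct, model_kind, grid, cfg1, fixed = fixed, init = theta0,
                    supersample = supersample)
  }
  if (!is.finite(out$residual) || out$residual > r0) {
    out <- fit_result(theta0, r0, out$iterations_used, FALSE,
                      init = "nn", model_kind = model_kind)
  } else {
    out$init <- "nn"
  }
  out
}

#' Convergence rule for iterative fitting
#'
#' An iterative run is declared converged when the relative loss reduction is
#' below `rtol` (default 0.5%) for `window` (default 5) consecutive
#' iterations.
#'
#' @param loss_history Numeric vector of per-iteration loss values.
#' @param window Number of consecutive small reductions required.
#' @param rtol Relative-reduction threshold.
#' @return Logical flag.
#' @export
check_convergence <- function(loss_history, window = 5L, rtol = 0.005) {
  n <- length(loss_history)
  if (n < window + 1L) return(FALSE)
  tail_vals <- loss_history[(n - window):n]
  red <- (tail_vals[-length(tail_vals)] - tail_vals[-1]) / tail_vals[-length(tail_vals)]
  all(red < rtol)
}
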