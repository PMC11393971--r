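test_that("convergence rule: five consecutive sub-0.5% reductions", {
  expect_true(check_convergence(c(1.0, 0.999, 0.9985, 0.998, 0.9979, 0.9978, 0.9977)))
  expect_false(check_convergence(1.0 * 0.9^(0:19)))   # 10% reductions
  expect_false(check_convergence(c(1.0, 0.999, 0.9985)))  # too short
})

test_that("gradient refinement is a guarded descent", {
  g <- test_grid()
  truth <- pk_params(0.2, 1.2, 0.05, 0.6)
  ct <- fmrdi_forward(truth, g)
  cfg <- fit_config("gradient_refine")

  # at the global minimum the gradient vanishes and nothing moves
  at_min <- refine(truth, ct, g, cfg)
  expect_equal(unname(at_min$params), unname(fmrdi:::pk_as_vector(truth)))
  expect_equal(at_min$residual, 0, tolerance = 1e-20)

  # zero step size returns the start unchanged
  cfg0 <- fit_config("gradient_refine", step_size = 0)
  p0 <- pk_params(0.25, 1.0, 0.05, 0.5)
  frozen <- refine(p0, ct, g, cfg0)
  expect_equal(unname(frozen$params), unname(fmrdi:::pk_as_vector(p0)))

  # a perturbed start strictly improves and never exceeds its own residual
  pert <- pk_params(0.22, 1.2, 0.05, 0.6)   # +10% on ktrans
  r0 <- squared_fit_error(ct, fmrdi_forward(pert, g))
  out <- refine(pert, ct, g, cfg)
  expect_lt(out$residual, r0)
  rel0 <- abs(0.22 - 0.2) / 0.2
  rel1 <- abs(out$params[["ktrans"]] - 0.2) / 0.2
  expect_lt(rel1, rel0)
  expect_lte(out$iterations_used, 20)
  # bounds always respected
  expect_true(out$params[["lambda_weight"]] >= 0 && out$params[["lambda_weight"]] <= 1)
})

test_that("residual gradient matches central finite differences", {
  g <- test_grid()
  set.seed(1234)
  ct <- fmrdi_forward(pk_params(0.2, 1, 0.04, 0.5), g)
  draws <- sample_pk_params(n = 20, seed = 88)
  draws$ktrans <- pmax(draws$ktrans, 0.01)
  draws$kep <- pmax(draws$kep, 0.05)
  draws$t0 <- pmax(draws$t0, 0.01)
  draws$lambda_weight <- pmin(pmax(draws$lambda_weight, 0.05), 0.95)
  free <- c("ktrans", "kep", "t0", "lambda_weight")
  for (i in seq_len(20)) {
    theta <- c(ktrans = draws$ktrans[i], kep = draws$kep[i], t0 = draws$t0[i],
               lambda_weight = draws$lambda_weight[i])
    gr <- fmrdi:::residual_gradient(theta, free, ct, "fmrdi", g)
    for (nm in free) {
      h <- 1e-6
      tp <- theta; tp[nm] <- theta[nm] + h
      tm <- theta; tm[nm] <- theta[nm] - h
      fd <- (sum((fmrdi:::kind_forward(tp, "fmrdi", g) - ct)^2) -
               sum((fmrdi:::kind_forward(tm, "fmrdi", g) - ct)^2)) / (2 * h)
      expect_lt(abs(gr$grad[[nm]] - fd) / max(abs(fd), 1e-6), 1e-4)
    }
  }
})

test_that("multi-restart NLLS recovers noise-free fMRDI parameters", {
  g <- test_grid()
  draws <- sample_pk_params(n = 10, seed = 555)
  for (i in seq_len(10)) {
    truth <- c(draws$ktrans[i], draws$kep[i], draws$lambda_weight[i])
    pk <- pk_params(draws$ktrans[i], draws$kep[i], draws$t0[i], draws$lambda_weight[i])
    fit <- nlls_fit(fmrdi_forward(pk, g), "fmrdi", g, fit_config(seed = i))
    est <- c(fit$params[["ktrans"]], fit$params[["kep"]], fit$params[["lambda_weight"]])
    expect_lt(sqrt(sum((est - truth)^2)) / sqrt(sum(truth^2)), 0.02)
  }
})

test_that("best-of-k residual never increases with more restarts", {
  g <- test_grid()
  b <- synthesize_batch(noise = noise_config(6, 6), n = 5, seed = 99)
  for (i in 1:5) {
    # same seed makes restart sets nested: k = 1 starts are a subset of k = 10
    res_k <- vapply(c(1L, 3L, 10L), function(k) {
      nlls_fit(b$curves[i, ], "fmrdi", g, fit_config(restarts = k, seed = 17))$residual
    }, 0)
    expect_true(all(diff(res_k) <= 1e-12))
  }
})

test_that("a zero curve drives the transfer constant to zero", {
  g <- test_grid()
  fit <- nlls_fit(rep(0, 75), "fmrdi", g, fit_config(restarts = 3, seed = 2))
  expect_lt(fit$params[["ktrans"]], 1e-4)
  expect_lt(fit$residual, 1e-8)
})

test_that("all model families fit their own noise-free curves", {
  g <- test_grid()
  cases <- list(
    list(kind = "tofts_parker",
         truth = c(ktrans = 0.2, kep = 1.1, t0 = 0.05)),
    list(kind = "mmrdi",
         truth = c(ktrans = 0.2, kep = 1.1, t0 = 0.05, lambda_transport = 8)),
    list(kind = "mrdi",
         truth = c(ktrans = 0.2, kep = 1.1, t0 = 0.05, kappa = 0.25, mu = 12))
  )
  for (cs in cases) {
    ct <- fmrdi:::kind_forward(cs$truth, cs$kind, g)
    fit <- nlls_fit(ct, cs$kind, g, fit_config(seed = 3))
    expect_lt(fit$residual / sum(ct^2), 1e-4)
  }
})

test_that("two-stage fit never degrades the network estimate", {
  g <- test_grid()
  m <- test_model()
  b <- synthesize_batch(n = 30, seed = 24680)
  cfg <- fit_config(seed = 1)
  for (i in 1:30) {
    ct <- b$curves[i, ]
    p0 <- drop(predict_pk(m, ct))
    p0 <- fmrdi:::clip_to_bounds(p0, cfg$bounds)
    r_nn <- squared_fit_error(ct, fmrdi:::kind_forward(p0, "fmrdi", g))
    fit <- two_stage_fit(m, ct, g, cfg)
    expect_lte(fit$residual, r_nn + 1e-12)
    expect_lte(fit$iterations_used, 20)
    expect_true(fit$params[["lambda_weight"]] >= 0 &&
                  fit$params[["lambda_weight"]] <= 1)
    expect_equal(fit$init, "nn")
  }
})

test_that("the gradient-refinement route of the two-stage fit also descends", {
  g <- test_grid()
  m <- test_model()
  b <- synthesize_batch(n = 5, seed = 1357)
  cfg <- fit_config("gradient_refine", seed = 1)
  for (i in 1:5) {
    ct <- b$curves[i, ]
    p0 <- drop(predict_pk(m, ct))
    p0 <- fmrdi:::clip_to_bounds(p0, cfg$bounds)
    r_nn <- squared_fit_error(ct, fmrdi:::kind_forward(p0, "fmrdi", g))
    fit <- two_stage_fit(m, ct, g, cfg)
    expect_lte(fit$residual, r_nn + 1e-12)
  }
})

test_that("fit configuration validates tolerances and bounds", {
  expect_error(fit_config(step_tolerance = 0), "positive")
  expect_error(fit_config(restarts = 0), "restarts")
  expect_error(fit_config(bounds = list(ktrans = c(2, 0))), "ordered")
  cfg <- fit_config(bounds = list(kep = c(0, 3)))
  expect_equal(cfg$bounds$kep, c(0, 3))
  expect_equal(cfg$bounds$ktrans, c(0, 2))
})
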