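test_that("time grid validates its invariants", {
  g <- time_grid()
  expect_equal(g$n_points, 75L)
  expect_equal(g$times[1], 0)
  expect_equal(diff(g$times), rep(5, 74))
  expect_error(time_grid(1), "n_points")
  expect_error(time_grid(10, 0), "dt")
  expect_error(time_grid(10, -1), "dt")
})

test_that("LDRW curve is zero before arrival and scales linearly in alpha", {
  g <- time_grid(40, 2)
  p <- ldrw_params(kappa = 0.3, mu = 10, t0_shift = 11)
  v <- evaluate_ldrw(g, p)
  expect_true(all(v[g$times <= 11] == 0))
  expect_true(all(v[g$times > 11] > 0))
  expect_true(all(is.finite(v)))
  p2 <- ldrw_params(kappa = 0.3, mu = 10, alpha = 2 * p$alpha, t0_shift = 11)
  expect_equal(evaluate_ldrw(g, p2), 2 * v)
})

test_that("LDRW mode matches the closed-form mode of the density", {
  # dense-grid argmax vs t* = (-1 + sqrt(1 + 4 k^2 mu^2)) / (2 k)
  kappa <- 0.3; mu <- 10
  dense <- time_grid(40001, 0.001)
  v <- evaluate_ldrw(dense, ldrw_params(kappa = kappa, mu = mu))
  t_hat <- dense$times[which.max(v)]
  t_star <- (-1 + sqrt(1 + 4 * kappa^2 * mu^2)) / (2 * kappa)
  expect_equal(t_star, 8.4713, tolerance = 1e-4)
  expect_lt(abs(t_hat - t_star), 0.001)
})

test_that("LDRW evaluation is pointwise (subsampling a dense grid is exact)", {
  p <- ldrw_params(kappa = 0.2, mu = 15, t0_shift = 3)
  g <- time_grid(75, 5)
  dense <- time_grid(741, 0.5)
  expect_equal(evaluate_ldrw(g, p), evaluate_ldrw(dense, p)[seq(1, 741, by = 10)])
})

test_that("LDRW parameters are validated", {
  expect_error(ldrw_params(kappa = -1), "positive")
  expect_error(ldrw_params(mu = 0), "positive")
  expect_error(ldrw_params(kappa = NaN), "finite|positive")
  expect_error(ldrw_params(t0_shift = -2), "t0_shift")
})

test_that("Parker population AIF has the expected shape", {
  g <- time_grid(24001, 0.1)  # dense, 40 min coverage not needed; 40 s steps
  v <- evaluate_parker(g)
  peak_idx <- which.max(v)
  peak_t_min <- g$times[peak_idx] / 60
  expect_gt(peak_t_min, 0.1)
  expect_lt(peak_t_min, 0.4)
  # value at t = 0 is a small fraction of the peak (1.3% with the literature
  # constants, computed by dense-grid evaluation)
  expect_lt(v[1] / max(v), 0.02)
  expect_gt(v[1] / max(v), 0.01)
  expect_true(all(v >= 0))
  expect_error(parker_params(sigma1 = 0), "positive")
  expect_error(parker_params(sigma1 = 0, sigma2 = 0), "positive")
})

test_that("transport kernel matches fine-grid quadrature of the convolution", {
  g <- test_grid()
  base <- evaluate_parker(g)
  fine_t <- seq(0, g$times[75], by = g$dt / 100)
  xi <- stats::approx(g$times, base, xout = fine_t)$y
  for (lt in c(2 * g$dt, 20)) {
    ker <- (1 / lt) * exp(-fine_t / lt)
    oracle <- vapply(seq(1, length(fine_t), by = 100), function(i) {
      v <- xi[1:i] * rev(ker[1:i])
      if (i == 1) 0 else (sum(v) - v[1] / 2 - v[i] / 2) * (g$dt / 100)
    }, 0)
    expect_lt(rel_l2(apply_transport(base, lt, g), oracle), 0.01)
  }
})

test_that("transport kernel limits: identity, area conservation, steady state", {
  g <- test_grid()
  base <- evaluate_fmrdi_aif(g, 0.5)   # zero at t = 0, so the limit is clean
  out <- apply_transport(base, g$dt / 100, g)
  expect_lt(rel_l2(out, base), 0.01)
  for (lt in c(1, 5, 20)) {
    expect_lte(sum(apply_transport(base, lt, g)) * g$dt, sum(base) * g$dt)
  }
  long <- time_grid(750, 5)
  steady <- apply_transport(rep(2, 750), 10, long)
  expect_equal(steady[750], 2, tolerance = 1e-9)
  expect_error(apply_transport(base, 0, g), "lambda_transport")
  expect_error(apply_transport(base, -3, g), "lambda_transport")
})

test_that("fMRDI weighted-sum AIF is affine in the dispersion weight", {
  g <- test_grid()
  fast <- evaluate_ldrw(g, fmrdi_fast_basis())
  slow <- evaluate_ldrw(g, fmrdi_slow_basis())
  expect_equal(evaluate_fmrdi_aif(g, 1), fast)
  expect_equal(evaluate_fmrdi_aif(g, 0), slow)
  expect_equal(evaluate_fmrdi_aif(g, 0.5), (fast + slow) / 2)
  for (lam in c(0.2, 0.7, 0.95)) {
    expect_equal(evaluate_fmrdi_aif(g, lam), lam * fast + (1 - lam) * slow)
  }
  expect_error(evaluate_fmrdi_aif(g, 1.2), "lambda_weight")
  expect_error(evaluate_fmrdi_aif(g, -0.1), "lambda_weight")
})

test_that("default LDRW bases are area-matched to the Parker AIF", {
  dense <- time_grid(80001, 0.005)
  parker_area_400 <- sum(evaluate_parker(dense)) * dense$dt
  for (basis in list(fmrdi_fast_basis(), fmrdi_slow_basis())) {
    basis_area <- sum(evaluate_ldrw(dense, basis)) * dense$dt
    expect_equal(basis_area, parker_area_400, tolerance = 1e-3)
  }
})

test_that("every AIF family evaluates nonnegative and finite on a grid", {
  g <- test_grid()
  specs <- list(
    aif_spec("parker"),
    aif_spec("ldrw"),
    aif_spec("mmrdi_transport", lambda_transport = 8),
    aif_spec("fmrdi_weighted", lambda_weight = 0.3)
  )
  for (spec in specs) {
    v <- eval_aif(spec, g)
    expect_true(all(is.finite(v)))
    expect_true(all(v >= 0))
  }
})

test_that("AIF specifications round-trip through plain lists (JSON-ready)", {
  specs <- list(
    aif_spec("parker"),
    aif_spec("ldrw", params = ldrw_params(0.2, 12)),
    aif_spec("mmrdi_transport", lambda_transport = 6),
    aif_spec("fmrdi_weighted", lambda_weight = 0.25)
  )
  g <- test_grid()
  for (spec in specs) {
    js <- jsonlite::toJSON(aif_spec_to_list(spec), auto_unbox = TRUE, digits = NA)
    back <- aif_spec_from_list(jsonlite::fromJSON(js))
    expect_equal(eval_aif(back, g), eval_aif(spec, g))
  }
  expect_error(aif_spec("mmrdi_transport", lambda_transport = -1), "lambda_transport")
})
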