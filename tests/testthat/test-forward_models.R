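test_that("degenerate transfer rates reduce to closed forms", {
  g <- test_grid()
  # no transfer -> identically zero tissue curve
  expect_equal(fmrdi_forward(pk_params(0, 1, 0, 0.5), g), rep(0, 75))
  # no washout -> Ktrans times the running (trapezoid) integral of the AIF
  cp <- evaluate_fmrdi_aif(g, 0.7)
  run_int <- (cumsum(cp) - cp / 2 - cp[1] / 2) * g$dt
  ct <- fmrdi_forward(pk_params(0.3, 0, 0, 0.7), g, supersample = 1)
  expect_equal(ct, 0.3 / 60 * run_int, tolerance = 1e-12)
})

test_that("exponential-AIF convolution matches the analytic solution", {
  g <- test_grid()
  beta <- 0.02            # 1/s
  kt <- 0.25; kep <- 1.0  # 1/min
  fine_t <- seq(0, g$times[75], by = g$dt / 10)
  cp <- exp(-beta * fine_t)
  keps <- kep / 60; kts <- kt / 60
  ana <- kts * (exp(-beta * g$times) - exp(-keps * g$times)) / (keps - beta)
  co <- fmrdi:::exp_conv_coeffs(keps, g$dt / 10)
  num <- (kts * fmrdi:::exp_conv_apply(cp, co))[seq(1, length(fine_t), by = 10)]
  expect_lt(rel_l2(num, ana), 0.005)
})

test_that("acquisition-grid forward model agrees with supersampled quadrature", {
  g <- test_grid()
  draws <- sample_pk_params(n = 10, seed = 301)
  for (i in seq_len(10)) {
    pk <- pk_params(draws$ktrans[i], draws$kep[i], draws$t0[i], draws$lambda_weight[i])
    coarse <- fmrdi_forward(pk, g, supersample = 10)
    dense <- fmrdi_forward(pk, g, supersample = 100)
    expect_lt(rel_l2(coarse, dense), 0.01)
  }
})

test_that("forward model is homogeneous in Ktrans and causal in t0", {
  g <- test_grid()
  pk1 <- pk_params(0.1, 0.8, 0.05, 0.4)
  pk3 <- pk_params(0.3, 0.8, 0.05, 0.4)
  expect_equal(3 * fmrdi_forward(pk1, g), fmrdi_forward(pk3, g), tolerance = 1e-12)
  # zero before bolus arrival (t0 = 0.2 min = 12 s)
  ct <- fmrdi_forward(pk_params(0.2, 1, 0.2, 0.5), g)
  expect_true(all(abs(ct[g$times <= 12]) < 1e-9))
  expect_true(all(ct >= 0))
})

test_that("time-to-peak decreases (weakly) with the dispersion weight", {
  g <- test_grid()
  ttp <- vapply(seq(0, 1, by = 0.1), function(lam) {
    g$times[which.max(fmrdi_forward(pk_params(0.2, 1.5, 0, lam), g))]
  }, 0)
  expect_true(all(diff(ttp) <= 0))
})

test_that("fMRDI forward model is affine in the dispersion weight", {
  g <- test_grid()
  base <- function(lam) fmrdi_forward(pk_params(0.15, 1.2, 0.03, lam), g)
  expect_equal(base(0.3), 0.3 * base(1) + 0.7 * base(0), tolerance = 1e-12)
  # and matches tofts_forward with the weighted AIF spec
  pk <- pk_params(0.15, 1.2, 0.03, 0.3)
  expect_equal(fmrdi_forward(pk, g),
               tofts_forward(pk, aif_spec("fmrdi_weighted"), g))
})

test_that("analytic forward Jacobian matches central finite differences", {
  g <- test_grid()
  draws <- sample_pk_params(n = 5, seed = 77)
  draws$t0 <- pmax(draws$t0, 0.02)  # keep clear of the t0 = 0 boundary kink
  for (i in seq_len(5)) {
    v <- c(draws$ktrans[i], draws$kep[i], draws$t0[i], draws$lambda_weight[i])
    fj <- fmrdi:::fmrdi_forward_jac(pk_params(v[1], v[2], v[3], v[4]), g)
    expect_equal(fj$values, fmrdi_forward(pk_params(v[1], v[2], v[3], v[4]), g))
    for (j in 1:4) {
      h <- 1e-5
      vp <- v; vp[j] <- v[j] + h
      vm <- v; vm[j] <- v[j] - h
      fd <- (fmrdi_forward(pk_params(vp[1], vp[2], vp[3], vp[4]), g) -
               fmrdi_forward(pk_params(vm[1], vm[2], vm[3], vm[4]), g)) / (2 * h)
      expect_lt(max(abs(fj$jac[, j] - fd)) / max(abs(fd)), 1e-4)
    }
  }
})

test_that("T1 series convert to concentration with clamping", {
  # no enhancement
  expect_equal(as.numeric(concentration_from_t1(rep(1.4, 10), 1.4)), rep(0, 10))
  # unit arithmetic: 1/T1 - 1/T10 = 4.5 with r1 = 4.5 -> 1 mmol/L
  t10 <- 1.0
  t1 <- 1 / (1 / t10 + 4.5)
  expect_equal(as.numeric(concentration_from_t1(t1, t10)), 1.0)
  # negative enhancement clamps to zero with a counted warning
  expect_warning(ct <- concentration_from_t1(c(1.0, 1.2, 0.9), 1.0), "clamped")
  expect_equal(as.numeric(ct), c(0, 0, (1 / 0.9 - 1) / 4.5))
  expect_equal(attr(ct, "n_clamped"), 1L)
  expect_error(concentration_from_t1(c(1, -1), 1), "T1")
  expect_error(concentration_from_t1(rep(1, 3), 0), "t10")
})

test_that("precontrast zeroing finds the frame before the steepest rise", {
  # unambiguous step: steepest rise arrives at frame 4, so frames 1..3 zero
  res <- zero_precontrast(c(0, 0, 0, 5, 5, 5, 5, 5))
  expect_equal(res$last_precontrast, 3L)
  expect_equal(res$curve, c(0, 0, 0, 5, 5, 5, 5, 5))
  # nonzero leading values actually get zeroed
  res2 <- zero_precontrast(c(0.1, 0.12, 0.1, 5, 5, 5, 5, 5))
  expect_equal(res2$curve[1:3], c(0, 0, 0))
  expect_equal(res2$curve[4:8], rep(5, 5))
  # flat curve: all differences tie, broken to the earliest frame
  expect_equal(zero_precontrast(rep(2, 20))$last_precontrast, 1L)
  expect_error(zero_precontrast(1.0), "length")
})

test_that("precontrast detection localizes a synthetic bolus arrival", {
  g <- test_grid()
  # t0 = 30 s = 0.5 min; frame index 7 (1-based) is the last precontrast frame
  ct <- tofts_forward(pk_params(0.3, 1, 0.5),
                      aif_spec("ldrw", params = fmrdi_fast_basis()), g)
  k <- zero_precontrast(ct)$last_precontrast
  expect_gte(k, 6L)
  expect_lte(k, 8L)
})

test_that("pk_params validates ranges", {
  expect_error(pk_params(-0.1, 1), ">= 0")
  expect_error(pk_params(0.1, -1), ">= 0")
  expect_error(pk_params(0.1, 1, lambda_weight = 1.5), "lambda_weight")
  expect_error(pk_params(NA, 1), "finite")
})
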