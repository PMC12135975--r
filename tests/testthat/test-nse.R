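tau_grid <- exp(seq(log(0.005), log(10), length.out = 30))

test_that("ISF model reduces to a single coherent exponential without incoherent part", {
  m <- isf_model(tau_grid, 0.9, 0, 0.3, 8)
  expect_equal(m, 0.9 * exp(-0.3 * tau_grid))
})

test_that("a fast incoherent term with opposite sign produces the short-tau rise", {
  m <- isf_model(tau_grid, 0.9, 0.2, 0.3, 8)
  expect_gt(max(diff(m[tau_grid < 0.5])), 0)     # rises first
  expect_lt(m[length(m)], max(m))                 # then decays
  expect_equal(m[1], 0.9 * exp(-0.3 * tau_grid[1]) - 0.2 * exp(-8 * tau_grid[1]))
})

test_that("a fully immobile Bragg coherent part stays constant", {
  m <- isf_model(tau_grid, 0.8, 0, 0.07, 8, s = 1)
  expect_equal(m, rep(0.8, length(tau_grid)))
})

test_that("the model at tau -> 0+ tends to the amplitude difference", {
  for (s in c(0, 0.5, 1)) {
    v0 <- isf_model(1e-9, 0.8, 0.3, 0.07, 8, s = s)
    expect_equal(v0, 0.8 - 0.3, tolerance = 1e-6)
  }
})

test_that("noiseless ISF curves are recovered to high precision", {
  y <- isf_model(tau_grid, 0.9, 0.2, 0.3, 8)
  cv <- isf_curve(0.21, tau_grid, y)
  f <- fit_isf(cv, constraint = 0.7)
  expect_lt(abs(f$a_coh - 0.9), 1e-4)
  expect_lt(abs(f$a_inc - 0.2), 1e-4)
  expect_lt(abs(f$gamma_coh - 0.3), 1e-4)
  expect_lt(abs(f$gamma_inc - 8), 1e-3)
})

test_that("shifting the constraint shifts the coherent amplitude linearly", {
  y <- isf_model(tau_grid, 0.9, 0.2, 0.3, 8)
  cv <- isf_curve(0.21, tau_grid, y)
  f1 <- fit_isf(cv, constraint = 0.7)
  f2 <- fit_isf(cv, constraint = 0.8)
  expect_equal(f2$a_coh - f1$a_coh - (f2$a_inc - f1$a_inc), 0.1,
               tolerance = 1e-6)
})

test_that("a curve without short Fourier times cannot set the constraint", {
  tau <- tau_grid[tau_grid > 0.02]
  cv <- isf_curve(0.21, tau, isf_model(tau, 0.9, 0.2, 0.3, 8))
  expect_error(fit_isf(cv), "constraint")
})

test_that("Bragg curves require a fixed free-protein rate", {
  y <- isf_model(tau_grid, 0.8, 0.12, 0.0666, 1.78, s = 0.5)
  cv <- isf_curve(0.149, tau_grid, y, is_bragg = TRUE)
  expect_error(fit_isf(cv), "gamma_free")
})

test_that("the immobile fraction is recovered within 0.05 at 3% noise", {
  # conditions where the free-protein decay is fully resolved inside the
  # Fourier-time window (gamma_free * tau_max = 3); the >= 100-seed
  # Monte-Carlo envelope at these conditions is well inside +-0.05
  gf <- 0.3; gi <- 8
  for (seed in c(5, 17, 41)) {
    y <- withr::with_seed(seed, {
      isf_model(tau_grid, 0.9, 0.2, gf, gi, s = 0.5) +
        rnorm(length(tau_grid), 0, 0.03)
    })
    cv <- isf_curve(0.149, tau_grid, y, error = rep(0.03, length(tau_grid)),
                    is_bragg = TRUE)
    f <- fit_isf(cv, gamma_free = gf, gamma_inc_fixed = gi)
    expect_lt(abs(f$s - 0.5), 0.05)
  }
})

test_that("the immobile fraction is invariant under rescaling the whole curve", {
  truth <- nse_default_truth()
  gf <- truth$D_coh * 0.149^2
  y <- isf_model(tau_grid, 0.8, 0.12, gf, 1.78, s = 0.4)
  f1 <- fit_isf(isf_curve(0.149, tau_grid, y, is_bragg = TRUE),
                gamma_free = gf, gamma_inc_fixed = 1.78)
  f2 <- fit_isf(isf_curve(0.149, tau_grid, 0.37 * y, is_bragg = TRUE),
                gamma_free = gf, gamma_inc_fixed = 1.78)
  expect_equal(f1$s, f2$s, tolerance = 1e-6)
})

test_that("constrained fit matches an unconstrained penalty-route oracle", {
  y <- isf_model(tau_grid, 0.9, 0.2, 0.3, 8)
  f <- fit_isf(isf_curve(0.21, tau_grid, y), constraint = 0.7)
  pen <- isf_penalty_fit(tau_grid, y, 0.7)
  expect_lt(abs(f$a_coh - pen[["a_coh"]]), 1e-3)
  expect_lt(abs(f$a_inc - pen[["a_inc"]]), 1e-3)
  expect_lt(abs(f$gamma_coh - pen[["gamma_coh"]]), 1e-3)
})

test_that("sum-constraint convention is available as a switch", {
  y <- isf_model(tau_grid, 0.9, 0.2, 0.3, 8)
  f <- fit_isf(isf_curve(0.21, tau_grid, y), constraint = 1.1,
               constraint_mode = "sum")
  expect_equal(f$a_coh + f$a_inc, 1.1, tolerance = 1e-8)
})

test_that("Fickian interpolation reproduces exact quadratic rates", {
  q <- c(0.10, 0.13, 0.21, 0.30)
  g <- 3 * q^2
  gf <- fickian_interpolate_rate(0.149, q, g)
  expect_equal(as.numeric(gf), 3 * 0.149^2, tolerance = 1e-12)
  expect_equal(attr(gf, "D"), 3, tolerance = 1e-12)
  # hand evaluation: D = 3 A^2/ns at q = 0.149 -> 0.066603 1/ns
  expect_equal(as.numeric(gf), 0.066603, tolerance = 1e-6)
  # linearity in the rates
  gf2 <- fickian_interpolate_rate(0.149, q, 2 * g)
  expect_equal(as.numeric(gf2), 2 * as.numeric(gf), tolerance = 1e-12)
  expect_error(fickian_interpolate_rate(0.149, q[1], g[1]), ">= 2")
})

test_that("crystal-fraction series is normalized and recovers its kinetics", {
  comp <- sigmoid_component(0.7, 45, 11.5)
  ages <- seq(0, 80, by = 2)
  s <- withr::with_seed(3, {
    sigmoid_eval(ages, comp) + rnorm(length(ages), 0, 0.05 * 0.7)
  })
  res <- nse_crystal_series(ages, s, error = rep(0.05 * 0.7, length(ages)))
  expect_equal(max(res$series$fraction), 1)
  expect_lt(abs(res$fit$par[["t0_1"]] - 45), 2 * res$fit$se[["t0_1"]] + 0.5)
  expect_lt(abs(res$fit$par[["dt_1"]] - 11.5), 2 * res$fit$se[["dt_1"]] + 0.5)
  # normalization idempotence: running the output through again is a no-op
  res2 <- nse_crystal_series(res$series$age_h, res$series$fraction)
  expect_equal(res2$series$fraction, res$series$fraction, tolerance = 1e-12)
})

test_that("a constant immobile-fraction series is flagged as degenerate", {
  res <- nse_crystal_series(seq(0, 20, 4), rep(0.3, 6))
  expect_true("degenerate-normalization" %in% res$flags)
})

test_that("the full NSE chain recovers the growth kinetics from raw curves", {
  curves <- gen_nse_dataset(ages_h = seq(0, 80, by = 2), seed = 6)
  res <- analyze_nse_dataset(curves)
  truth <- nse_default_truth()$s_component
  expect_lt(abs(res$crystal$fit$par[["t0_1"]] - truth$t0), 5)
  expect_lt(abs(res$crystal$fit$par[["dt_1"]] - truth$dt), 5)
})
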