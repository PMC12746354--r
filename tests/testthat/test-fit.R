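# Interference-parameter fitting: RMSE metric, noiseless self-consistency
# recovery, degenerate truth, determinism, and the fitted-model S3 surface.

test_that("curve RMSE matches hand arithmetic and rejects grid mismatch", {
  g <- c(0, 20, 40)
  a <- spoiling_curve(g, c(50, 51, 52))
  expect_equal(as.numeric(rmse_curves(a, a)), 0)

  b <- spoiling_curve(g, c(52, 53, 54))
  expect_equal(as.numeric(rmse_curves(a, b)), 2)

  c2 <- spoiling_curve(c(0, 20), c(53, 55))
  d2 <- spoiling_curve(c(0, 20), c(50, 51))
  expect_equal(as.numeric(rmse_curves(c2, d2)), sqrt((9 + 16) / 2),
               tolerance = 1e-12)

  expect_error(rmse_curves(a, c2), "grids differ")

  # failed points drop out of the mean
  e <- spoiling_curve(g, c(50, NA, 52))
  expect_equal(attr(rmse_curves(a, e), "n_points"), 2L)
})

test_that("noiseless self-consistency fit recovers the generating parameters", {
  comp <- pvp5_components_3t()
  prot <- afi_protocol(te_ms = 1.9)
  sys <- pvp5_system_3t()
  truth <- pvp5_params_3t()
  cmb <- combine_components(comp, truth)
  measured <- spoiling_curve(cmb$phi0_deg, cmb$alpha_deg,
                             provenance = "synthetic-measured")
  fit <- fit_interference(measured, prot, sys, components = comp)
  expect_lt(abs(fit$params$w - truth$w), 0.005)
  expect_lt(abs(fit$params$phi - truth$phi), 0.02 * pi)
  expect_lt(fit$rmse, 0.1)
})

test_that("w = 0 truth yields a near-zero fitted weight and rmse", {
  comp <- pvp5_components_3t()
  prot <- afi_protocol(te_ms = 1.9)
  sys <- pvp5_system_3t()
  zero <- interference_params(w = 0, phi = 0, delta_nu_hz = 320)
  cmb <- combine_components(comp, zero)
  measured <- spoiling_curve(cmb$phi0_deg, cmb$alpha_deg)
  fit <- fit_interference(measured, prot, sys, components = comp)
  expect_lte(fit$params$w, 0.005)
  expect_lt(fit$rmse, 0.05)
})

test_that("fitting is deterministic: same data, same settings, same result", {
  comp <- pvp5_components_3t()
  prot <- afi_protocol(te_ms = 1.9)
  sys <- pvp5_system_3t()
  cmb <- combine_components(comp, pvp5_params_3t())
  measured <- spoiling_curve(cmb$phi0_deg, cmb$alpha_deg)
  f1 <- fit_interference(measured, prot, sys, components = comp)
  f2 <- fit_interference(measured, prot, sys, components = comp)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$rmse, f2$rmse)
})

test_that("noisy replicates recover the weight within the stated tolerance", {
  comp <- pvp5_components_3t()
  prot <- afi_protocol(te_ms = 1.9)
  sys <- pvp5_system_3t()
  truth <- interference_params(w = 0.1, phi_pi = -0.18, delta_nu_hz = 320)
  errs <- vapply(1:20, function(seed) {
    meas <- generate_measured_curve(
      prot, sys, truth, truth_alpha = 60,
      noise = noise_model(complex_noise_sd = 5e-4, n_voxels = 100,
                          seed = seed),
      components = comp)
    fit <- fit_interference(meas, prot, sys, components = comp)
    abs(fit$params$w - truth$w)
  }, numeric(1))
  expect_lte(median(errs), 0.02)
})

test_that("failed measured points are excluded and reported", {
  comp <- pvp5_components_3t()
  prot <- afi_protocol(te_ms = 1.9)
  sys <- pvp5_system_3t()
  cmb <- combine_components(comp, pvp5_params_3t())
  alpha <- cmb$alpha_deg
  alpha[c(2, 9)] <- NA
  measured <- spoiling_curve(cmb$phi0_deg, alpha)
  fit <- fit_interference(measured, prot, sys, components = comp)
  expect_equal(fit$diagnostics$excluded, c(20, 160))
  expect_equal(fit$n_points, 8L)
  expect_lt(abs(fit$params$w - 0.136), 0.005)
})

test_that("a fit needs at least four successful measured points", {
  g <- seq(0, 180, by = 20)
  bad <- spoiling_curve(g, c(50, 51, 52, rep(NA_real_, 7)))
  expect_error(
    fit_interference(bad, afi_protocol(), pvp5_system_3t()),
    "at least 4")
})

test_that("the fitted-model object supports the standard methods", {
  comp <- pvp5_components_3t()
  prot <- afi_protocol(te_ms = 1.9)
  sys <- pvp5_system_3t()
  cmb <- combine_components(comp, pvp5_params_3t())
  measured <- spoiling_curve(cmb$phi0_deg, cmb$alpha_deg)
  fit <- fit_interference(measured, prot, sys, components = comp)

  expect_named(coef(fit), c("w", "phi", "delta_nu_hz"))
  expect_equal(length(residuals(fit)), 10)
  expect_lt(max(abs(residuals(fit))), 0.1)
  expect_equal(fitted(fit), fit$fitted_curve$alpha_deg)

  pred <- predict(fit)
  expect_s3_class(pred, "spoiling_curve")
  expect_equal(pred$alpha_deg, fitted(fit))

  expect_output(print(fit), "Two-frequency interference fit")
  expect_output(print(summary(fit)), "Runner-up")

  reps <- simulate(fit, nsim = 2, seed = 42)
  expect_length(reps, 2)
  expect_s3_class(reps[[1]], "spoiling_curve")
  # different seeds give different noise draws
  expect_false(identical(reps[[1]]$alpha_deg, reps[[2]]$alpha_deg))

  pdf_file <- tempfile(fileext = ".pdf")
  grDevices::pdf(pdf_file)
  expect_no_error(plot(fit))
  grDevices::dev.off()
})
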