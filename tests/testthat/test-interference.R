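# Two-frequency interference model: combination algebra, TE-beat structure
# and the limiting behaviors of the off-resonant pool.

test_that("parameter and system constructors validate their inputs", {
  p <- interference_params(w = 0.136, phi_pi = -0.18, delta_nu_hz = 320)
  expect_equal(p$phi, -0.18 * pi)
  expect_error(interference_params(w = -0.1, phi = 0), "w >= 0")
  expect_error(interference_params(w = 0.1), "exactly one")
  # phase wrapping onto (-pi, pi]
  expect_equal(interference_params(w = 0, phi = 3 * pi)$phi, pi)

  res <- tissue_component(1292, 780, 990)
  off <- tissue_component(100, 5.7, 990, delta_nu_hz = 320)
  expect_s3_class(two_component_system(res, off), "two_component_system")
  expect_error(two_component_system(off, off), "delta_nu_hz = 0")
  expect_error(two_component_system(res, res), "delta_nu_hz != 0")
  expect_error(
    two_component_system(res, tissue_component(100, 5.7, 500, 320)),
    "same ADC")
})

test_that("signal combination has the stated degenerate and periodic limits", {
  pars <- interference_params(w = 0, phi = 0.4, delta_nu_hz = 320)
  expect_equal(combine_signals(0.3 + 0.1i, 1i, pars, 1.9), 0.3 + 0.1i)

  unit <- interference_params(w = 1, phi = 0, delta_nu_hz = 320)
  expect_equal(combine_signals(0 + 0i, 0.2 - 0.5i, unit, 0), 0.2 - 0.5i)

  pars2 <- interference_params(w = 0.2, phi = 1.1, delta_nu_hz = 320)
  te <- 2.3
  expect_equal(combine_signals(0.3 + 0.1i, 1i, pars2, te),
               combine_signals(0.3 + 0.1i, 1i, pars2, te + 1000 / 320),
               tolerance = 1e-12)
})

test_that("w = 0 two-component estimate equals the single-component estimate", {
  p <- afi_protocol(phi0_deg = 120)
  sys <- pvp5_system_3t()
  pars0 <- interference_params(w = 0, phi = 0, delta_nu_hz = 320)
  two <- simulate_afi_two_component(p, sys, pars0)
  one <- simulate_afi(p, sys$res)
  expect_equal(afi_flip_angle(two, p$n), afi_flip_angle(one, p$n),
               tolerance = 1e-12)
})

test_that("combined signal magnitude beats in TE with period 1/delta_nu", {
  # under complete spoiling both pools give TE-independent recorded signals
  # (up to T2 decay), so |S(TE)| is a sampled sinusoid of period 1/dnu
  set_ps <- afi_settings(perfect_spoiling = TRUE)
  p <- afi_protocol(phi0_deg = 120)
  # equal T2 in both pools removes the differential T2 envelope so the
  # periodicity is exact, not just sinusoid-like
  sys <- suppressWarnings(two_component_system(
    tissue_component(1292, 780, 990),
    tissue_component(100, 780, 990, delta_nu_hz = 320)))  # deliberate T2 > T1
  pars <- pvp5_params_3t()
  dnu <- 320
  period <- 1000 / dnu                                   # 3.125 ms
  te <- seq(1.5, 1.5 + period, length.out = 9)
  s1 <- vapply(te, function(t) {
    pr <- p; pr$te_ms <- t
    Mod(simulate_afi_two_component(pr, sys, pars, set_ps)$s1)
  }, numeric(1))
  # strip the common T2 decay, then compare shifted by one full period
  osc <- s1 / exp(-te / 780)
  expect_equal(osc[1], osc[9], tolerance = 1e-4)
  # and it genuinely oscillates
  expect_gt(diff(range(osc)) / mean(osc), 0.05)
})

test_that("a very short T2 off pool is insensitive to the spoiling increment", {
  # transverse coherence dies before the next pulse: FID-like steady state
  off_fast <- tissue_component(100, 0.4, 990, delta_nu_hz = 320)
  mags <- vapply(c(0, 60, 117), function(p0) {
    p <- afi_protocol(phi0_deg = p0)
    s <- simulate_afi(p, off_fast, afi_settings(record = "pulse"))
    Mod(s$s1)
  }, numeric(1))
  expect_lt(diff(range(mags)) / mean(mags), 1e-6)
})

test_that("two-component flip angle depends on TE (unlike single-component)", {
  sys <- pvp5_system_3t()
  pars <- pvp5_params_3t()
  est <- vapply(c(1.9, 3.0), function(te) {
    p <- afi_protocol(te_ms = te, phi0_deg = 120)
    afi_flip_angle(simulate_afi_two_component(p, sys, pars), p$n)
  }, numeric(1))
  expect_gt(abs(est[1] - est[2]), 1)
})
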