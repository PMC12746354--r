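# AFI sequence layer: phase schedule, moment conversion, flip-angle
# estimator, and the simulator against scalar and isochromat oracles.

test_that("RF phase schedule follows the quadratic recurrence", {
  expect_equal(rf_phase_schedule(0, 5), rep(0, 5))
  expect_equal(rf_phase_schedule(120, 4), c(120, 0, 0, 120))

  # recurrence equals the closed form for a long train
  phi0 <- 117
  n <- 1000
  rec <- numeric(n)
  ph <- 0
  for (j in 1:n) {
    ph <- (ph + j * phi0) %% 360
    rec[j] <- ph
  }
  expect_equal(rf_phase_schedule(phi0, n), rec)
})

test_that("moment conversion reproduces the printed dephasing values", {
  k20pi <- moment_to_orders(117.5, 2.0)
  expect_equal(as.integer(k20pi), 10L)
  expect_equal(attr(k20pi, "pi_multiples"), 20, tolerance = 0.005)

  expect_equal(as.integer(moment_to_orders(11.75, 2.0)), 1L)
  expect_equal(as.integer(moment_to_orders(0, 2.0)), 0L)
  # all four named moment sets are valid multiples
  for (m in moment_sets()) {
    expect_no_error(moment_to_orders(m[1], 2.0))
    expect_no_error(moment_to_orders(m[2], 2.0))
  }
  expect_error(moment_to_orders(17, 2.0), "nearest valid")
})

test_that("flip-angle estimator inverts the ideal ratio and flags failures", {
  expect_equal(afi_flip_angle(1, 5, s2 = 7 / 11), 60, tolerance = 1e-12)
  expect_equal(afi_flip_angle(1, 5, s2 = 1), 0)
  expect_true(is.na(afi_flip_angle(1, 5, s2 = 1.2)))
  expect_error(afi_flip_angle(0, 5, s2 = 1), "zero")
  expect_error(afi_flip_angle(1, 5, s2 = 5), "degenerate")

  # invariance under a global receiver phase rotation
  s1 <- 0.11 * exp(1i * 0.3); s2 <- 0.07 * exp(1i * 1.2)
  rot <- exp(1i * 2.2)
  expect_equal(afi_flip_angle(s1, 5, s2 = s2),
               afi_flip_angle(s1 * rot, 5, s2 = s2 * rot))
})

test_that("protocol validation catches inconsistent timing and moments", {
  expect_error(afi_protocol(te_ms = 30), "te_ms")
  expect_error(afi_protocol(tr2_ms = 110), "integer ratio")
  expect_error(afi_protocol(a_g1 = 100), "nearest valid")
  p <- afi_protocol()
  expect_equal(p$n, 5L)
  expect_equal(as.integer(p$dk1), 10L)
  expect_equal(as.integer(p$dk2), 50L)
})

test_that("perfect-spoiling simulation matches the longitudinal recursion", {
  set_fast <- afi_settings(perfect_spoiling = TRUE)
  for (alpha in c(20, 45, 70)) {
    for (t1 in c(410, 2347)) {
      p <- afi_protocol(alpha_deg = alpha, phi0_deg = 120)
      tis <- tissue_component(t1, 100, 0)
      sig <- simulate_afi(p, tis, set_fast)
      r <- Mod(sig$s2) / Mod(sig$s1)
      expect_equal(r, ideal_spoiling_ratio(alpha, 25, 125, t1),
                   tolerance = 1e-10)
    }
  }
})

test_that("flip-angle round trip under ideal spoiling stays within the short-TR bias", {
  set_fast <- afi_settings(perfect_spoiling = TRUE)
  for (alpha in c(20, 45, 70)) {
    for (t1 in c(410, 1301, 2347)) {
      p <- afi_protocol(alpha_deg = alpha)
      sig <- simulate_afi(p, tissue_component(t1, 100, 0), set_fast)
      est <- afi_flip_angle(sig, p$n)
      expect_lt(abs(est - alpha) / alpha, 0.02)
    }
  }
})

test_that("single-component flip angle is independent of TE", {
  # TE scales S1 and S2 identically, so the ratio estimator is exactly
  # TE-invariant. Diffusion is excluded here: the spoiler occupies [TE, TR],
  # so with ADC > 0 the echo time weakly modulates the diffusion weighting
  # (~0.3% on alpha), which is a property of the spoiler timing, not of the
  # estimator.
  w1 <- tissue_component(1301, 585, 0)
  est <- vapply(c(1.5, 6.1), function(te) {
    p <- afi_protocol(te_ms = te, phi0_deg = 120)
    afi_flip_angle(simulate_afi(p, w1), p$n)
  }, numeric(1))
  expect_equal(est[1], est[2], tolerance = 1e-6)
})

test_that("EPG and isochromat simulators agree without diffusion", {
  tis <- tissue_component(1301, 585, 0)
  for (phi0 in c(90, 120)) {
    p <- afi_protocol(phi0_deg = phi0)
    e <- simulate_afi(p, tis)
    i <- simulate_afi_isochromat(p, tis, n_spins = 4096)
    expect_equal(Mod(i$s1), Mod(e$s1), tolerance = 1e-3)
    expect_equal(Mod(i$s2), Mod(e$s2), tolerance = 1e-3)
  }
})

test_that("isochromat discretization is converged at the default density", {
  # short-T2 pool: configuration orders die out well below the spin count
  tis <- tissue_component(800, 100, 0)
  p <- afi_protocol(phi0_deg = 120)
  a <- simulate_afi_isochromat(p, tis, n_spins = 2000)
  b <- simulate_afi_isochromat(p, tis, n_spins = 4000)
  expect_lt(abs(Mod(a$s1) - Mod(b$s1)) / Mod(b$s1), 1e-4)
  expect_lt(abs(Mod(a$s2) - Mod(b$s2)) / Mod(b$s2), 1e-4)
})

test_that("truncation overflow aborts with a clear error", {
  p <- afi_protocol(phi0_deg = 120)
  tis <- tissue_component(1301, 585, 0)       # no diffusion damping
  expect_error(simulate_afi(p, tis, afi_settings(k_max = 64)),
               "truncation loss")
})
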