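# The four elementary EPG operators against closed forms, the standard
# rotation algebra and a stepwise Bloch integration of the hard pulse.

test_that("equilibrium state and trivial rotations behave as identities", {
  s <- epg_state()
  expect_equal(s$z[1], 1 + 0i)
  expect_equal(epg_transverse_energy(s), 0)

  id <- epg_rf(s, 0, 45)
  expect_equal(id$fp, s$fp)
  expect_equal(id$z, s$z)

  inv <- epg_rf(s, 180, 0)
  expect_equal(Re(inv$z[1]), -1, tolerance = 1e-12)
  expect_lt(epg_transverse_energy(inv), 1e-24)
})

test_that("on-resonance rotation matches the closed-form EPG matrix", {
  for (case in list(c(60, 0), c(37.3, 112), c(90, 270), c(133, -45))) {
    T_pkg <- afisim:::cartesian_to_epg_basis(
      afisim:::rf_pulse_rotation(case[1], case[2]))
    T_ref <- epg_rotation_closed_form(case[1], case[2])
    expect_equal(T_pkg, T_ref, tolerance = 1e-12)
  }
})

test_that("order-0 conjugate consistency survives arbitrary pulses", {
  s <- random_epg_state(n = 5, seed = 7)
  s <- epg_rf(s, 71, 33, 0.5, 150)
  expect_equal(s$fm[1], Conj(s$fp[1]), tolerance = 1e-12)
})

test_that("off-resonant hard pulse equals stepwise Bloch integration", {
  # 60 deg nominal, 0.5 ms rectangular pulse, 747 Hz off resonance
  s <- epg_rf(epg_state(), 60, 0, 0.5, 747)
  m <- bloch_rk4(c(0, 0, 1), 60, 0, 0.5, 747)
  expect_equal(Re(s$fp[1]), m[1], tolerance = 1e-9)
  expect_equal(Im(s$fp[1]), m[2], tolerance = 1e-9)
  expect_equal(Re(s$z[1]), m[3], tolerance = 1e-9)

  # nonzero phase too
  s2 <- epg_rf(epg_state(), 85, 130, 0.5, 320)
  m2 <- bloch_rk4(c(0, 0, 1), 85, 130, 0.5, 320)
  expect_equal(Re(s2$fp[1]), m2[1], tolerance = 1e-9)
  expect_equal(Im(s2$fp[1]), m2[2], tolerance = 1e-9)
})

test_that("off-resonance rotation is continuous at delta_nu -> 0", {
  T_on <- afisim:::cartesian_to_epg_basis(afisim:::rf_pulse_rotation(60, 30))
  T_off <- afisim:::cartesian_to_epg_basis(
    afisim:::rf_pulse_rotation(60, 30, 0.5, 1e-6))
  expect_equal(T_on, T_off, tolerance = 1e-8)
})

test_that("off-resonant rotation without pulse duration is rejected", {
  expect_error(epg_rf(epg_state(), 60, 0, 0, 747), "duration")
})

test_that("relaxation: identity, fixed point and half recovery", {
  s <- random_epg_state(n = 4, seed = 2)
  expect_equal(epg_relax(s, 0, 1000, 100), s)

  eq <- epg_state()
  expect_equal(epg_relax(eq, 314, 1000, 100), eq)

  z0 <- epg_rf(epg_state(), 90, 0)         # z[0] = 0 after 90 deg
  rec <- epg_relax(z0, 1000 * log(2), 1000, 100)
  expect_equal(Re(rec$z[1]), 0.5, tolerance = 1e-12)

  expect_error(epg_relax(s, -1, 1000, 100), "negative")
})

test_that("relaxation and diffusion never increase transverse energy", {
  s <- random_epg_state(n = 8, seed = 3)
  e0 <- epg_transverse_energy(s)
  expect_lte(epg_transverse_energy(epg_relax(s, 17, 800, 90)), e0)
  expect_lte(epg_transverse_energy(epg_diffusion(s, 3, 20, 1500, 2)), e0)
})

test_that("gradient shift: definition, identity and exact invertibility", {
  s <- epg_state()
  expect_equal(epg_shift(s, 0), s)

  # pure F(0) = c moves to F(1)
  c0 <- 0.3 - 0.4i
  s$fp[1] <- c0; s$fm[1] <- Conj(c0)
  sh <- epg_shift(s, 1)
  expect_equal(sh$fp[2], c0)
  expect_equal(sh$fp[1], 0 + 0i)
  expect_equal(sh$fm[1], Conj(sh$fp[1]))

  # +3 then -3 recovers random states exactly while below k_max
  for (seed in 1:5) {
    r <- random_epg_state(n = 6, k_max = 64, seed = seed)
    rt <- epg_shift(epg_shift(r, 3), -3)
    n <- length(r$fp)
    expect_equal(rt$fp[1:n], r$fp, tolerance = 1e-15)
    expect_equal(rt$fm[1:n], r$fm, tolerance = 1e-15)
    expect_equal(rt$z[1:n], r$z, tolerance = 1e-15)
  }
})

test_that("shift past k_max accumulates truncation loss", {
  s <- epg_state(k_max = 4)
  s$fp[1] <- 1 + 0i; s$fm[1] <- 1 + 0i
  sh <- epg_shift(s, 6)
  expect_gt(sh$trunc_loss, 0)
})

test_that("diffusion damping matches the scalar closed form", {
  # single F+(k = 10) state, no shift
  s <- afisim:::epg_pad(epg_state(), 11)
  s$fp[11] <- 1 + 0i
  adc <- 1930; interval <- 23.1; voxel <- 2
  d <- epg_diffusion(s, 0, interval, adc, voxel)
  expected <- exp(-(adc * 1e-12) * (2 * pi * 10 / (voxel * 1e-3))^2 *
                    interval * 1e-3)
  expect_equal(Mod(d$fp[11]), expected, tolerance = 1e-12)

  # adc = 0 and k = 0, dk = 0 are identities
  expect_equal(epg_diffusion(s, 5, 10, 0, 2), s)
  s0 <- epg_state(); s0$fp[1] <- 0.5 + 0i; s0$fm[1] <- 0.5 + 0i
  d0 <- epg_diffusion(s0, 0, 50, 2000, 2)
  expect_equal(d0$fp[1], s0$fp[1])

  expect_error(epg_diffusion(s, 1, 10, -5, 2), "negative")
})

test_that("precession advances F+ by the scalar phase factor", {
  s <- epg_state(); s$fp[1] <- 1 + 0i; s$fm[1] <- 1 + 0i
  expect_equal(epg_precess(s, 0, 5), s)

  pr <- epg_precess(s, 320, 1.9)
  expect_equal(Arg(pr$fp[1]), afisim:::wrap_pi(-2 * pi * 0.608),
               tolerance = 1e-12)
  expect_equal(pr$fm[1], Conj(pr$fp[1]))

  # full revolution: duration = 1/delta_nu
  full <- epg_precess(s, 320, 1000 / 320)
  expect_equal(full$fp[1], s$fp[1], tolerance = 1e-12)
})

test_that("operator compositions from equilibrium stay physical", {
  s <- epg_state()
  set.seed(11)
  for (i in 1:30) {
    s <- epg_rf(s, runif(1, 0, 180), runif(1, 0, 360), 0.5, 320)
    s <- epg_relax(s, runif(1, 0, 30), 1292, 780)
    s <- epg_diffusion(s, 10, 5, 990, 2)
    s <- epg_shift(s, sample(c(-2, 1, 3), 1))
    s <- epg_precess(s, 320, runif(1, 0, 10))
    expect_lte(Mod(s$z[1]), 1 + 1e-12)
    expect_lte(epg_transverse_energy(s), 1 + 1e-12)
  }
})
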