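# Independent oracles used across the test files. These deliberately avoid
# the package's own operator implementations: the Bloch oracle integrates the
# rotating-frame equation of motion numerically, the closed-form EPG rotation
# matrix is written out from the standard algebra, and the dual-TR ratio
# oracle is a scalar longitudinal recursion.

# RK4 integration of dM/dt = Omega x M for a rectangular pulse with
# Omega = (w1*cos(phi), w1*sin(phi), -2*pi*dnu), w1 = alpha/tau.
bloch_rk4 <- function(m0 = c(0, 0, 1), flip_deg, phase_deg = 0, pulse_ms,
                      delta_nu_hz = 0, n_steps = 4000) {
  tau <- pulse_ms * 1e-3
  w1 <- flip_deg * pi / 180 / tau
  phi <- phase_deg * pi / 180
  omega <- c(w1 * cos(phi), w1 * sin(phi), -2 * pi * delta_nu_hz)
  f <- function(m) c(omega[2] * m[3] - omega[3] * m[2],
                     omega[3] * m[1] - omega[1] * m[3],
                     omega[1] * m[2] - omega[2] * m[1])
  h <- tau / n_steps
  m <- m0
  for (i in seq_len(n_steps)) {
    k1 <- f(m)
    k2 <- f(m + h / 2 * k1)
    k3 <- f(m + h / 2 * k2)
    k4 <- f(m + h * k3)
    m <- m + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  m
}

# Standard closed-form on-resonance EPG rotation matrix in the (F+, F-, Z)
# basis for flip alpha (deg) about the axis at azimuth phi (deg).
epg_rotation_closed_form <- function(alpha_deg, phi_deg) {
  a <- alpha_deg * pi / 180
  p <- phi_deg * pi / 180
  matrix(c(
    cos(a / 2)^2, exp(2i * p) * sin(a / 2)^2, -1i * exp(1i * p) * sin(a),
    exp(-2i * p) * sin(a / 2)^2, cos(a / 2)^2, 1i * exp(-1i * p) * sin(a),
    -0.5i * exp(-1i * p) * sin(a), 0.5i * exp(1i * p) * sin(a), cos(a)
  ), 3, 3, byrow = TRUE)
}

# Steady-state dual-TR signal ratio |S2|/|S1| under ideal spoiling, from the
# scalar longitudinal recursion (z before the TR1 pulse and before the TR2
# pulse solve a 2x2 linear fixed point).
ideal_spoiling_ratio <- function(alpha_deg, tr1_ms, tr2_ms, t1_ms) {
  c_ <- cos(alpha_deg * pi / 180)
  e1 <- exp(-tr1_ms / t1_ms)
  e2 <- exp(-tr2_ms / t1_ms)
  z1 <- (c_ * e2 * (1 - e1) + 1 - e2) / (1 - c_^2 * e1 * e2)
  z2 <- z1 * c_ * e1 + (1 - e1)
  z2 / z1
}

# Random small EPG state with populated orders up to n (used for operator
# property tests). Order-0 transverse consistency is enforced.
random_epg_state <- function(n = 6, k_max = 64, seed = 1) {
  set.seed(seed)
  s <- epg_state(k_max = k_max)
  s <- afisim:::epg_pad(s, n + 1)
  s$fp <- complex(real = rnorm(n + 1), imaginary = rnorm(n + 1))
  s$fm <- complex(real = rnorm(n + 1), imaginary = rnorm(n + 1))
  s$z <- complex(real = rnorm(n + 1), imaginary = rnorm(n + 1))
  s$fm[1] <- Conj(s$fp[1])
  s$z[1] <- complex(real = Re(s$z[1]))
  s
}

# Shared simulation fixtures (memoized so several test files reuse the same
# component tables without re-simulating).
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(key, fun) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- fun()
  .fixture_env[[key]]
}

pvp5_system_3t <- function() {
  two_component_system(tissue_component(1292, 780, 990),
                       tissue_component(100, 5.7, 990, delta_nu_hz = 320))
}

pvp5_params_3t <- function() {
  interference_params(w = 0.136, phi_pi = -0.18, delta_nu_hz = 320)
}

pvp5_components_3t <- function() {
  fixture("pvp5_components_3t", function() {
    simulate_components(afi_protocol(te_ms = 1.9), pvp5_system_3t(),
                        phi0 = seq(0, 180, by = 20))
  })
}
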