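# Extended phase graph (EPG) engine.
#
# The state holds complex configuration amplitudes over non-negative integer
# dephasing orders k: F+(k), F-(k) = Conj(F(-k)), and Z(k). One order
# corresponds to 2*pi of dephasing across the voxel. Vectors grow on demand;
# a hard cap k_max bounds storage, and transverse energy shifted past the cap
# is accumulated in a truncation-loss counter.

#' Create an EPG configuration state set
#'
#' Constructs the thermal-equilibrium extended-phase-graph state: all
#' transverse configuration amplitudes zero, longitudinal order zero equal to
#' the equilibrium magnetization `m0`.
#'
#' @param k_max Maximum storable dephasing order. Amplitudes shifted beyond
#'   this order are dropped and their energy recorded in the truncation-loss
#'   counter.
#' @param m0 Equilibrium magnetization (dimensionless scale of the signal).
#' @return An object of class `epg_state` with fields `fp`, `fm`, `z`
#'   (complex amplitude vectors indexed by order k = 0, 1, ...), `k_max`,
#'   `m0` and `trunc_loss` (summed squared magnitude lost past `k_max`).
#' @examples
#' s <- epg_state()
#' s <- epg_rf(s, 60, 0)
#' Mod(s$fp[1])  # sin(60 deg) transverse amplitude
#' @export
epg_state <- function(k_max = 4096, m0 = 1) {
  stopifnot(k_max >= 1, m0 > 0)
  structure(
    list(
      fp = complex(1),
      fm = complex(1),
      z = as.complex(m0),
      k_max = as.integer(k_max),
      m0 = m0,
      trunc_loss = 0
    ),
    class = "epg_state"
  )
}

#' @export
print.epg_state <- function(x, ...) {
  n <- length(x$fp) - 1L
  cat("<epg_state> orders 0..", n, " (cap ", x$k_max, ")\n", sep = "")
  cat(sprintf("  F+(0) = %.4g%+.4gi   Z(0) = %.4g\n",
              Re(x$fp[1]), Im(x$fp[1]), Re(x$z[1])))
  cat(sprintf("  transverse energy = %.4g, truncation loss = %.3g\n",
              epg_transverse_energy(x), x$trunc_loss))
  invisible(x)
}

#' Total transverse configuration energy
#'
#' Sum of squared magnitudes of all F+ and F- amplitudes. Never increases
#' under relaxation or diffusion.
#'
#' @param state An `epg_state`.
#' @return Numeric scalar.
#' @export
epg_transverse_energy <- function(state) {
  sum(Mod(state$fp)^2) + sum(Mod(state$fm)^2)
}

# Pad all three amplitude vectors to a common length n (orders 0..n-1).
epg_pad <- function(state, n) {
  add <- n - length(state$fp)
  if (add > 0) {
    zc <- complex(add)
    state$fp <- c(state$fp, zc)
    state$fm <- c(state$fm, zc)
    state$z <- c(state$z, zc)
  }
  state
}

# Drop trailing orders whose amplitudes are all below tol (keeps order 0).
epg_trim <- function(state, tol = 1e-16) {
  a <- pmax(Mod(state$fp), Mod(state$fm), Mod(state$z))
  keep <- which(a > tol)
  n <- if (length(keep)) max(keep) else 1L
  if (n < length(state$fp)) {
    state$fp <- state$fp[seq_len(n)]
    state$fm <- state$fm[seq_len(n)]
    state$z <- state$z[seq_len(n)]
  }
  state
}

# Right-handed rotation matrix about unit axis u by angle beta (Rodrigues).
rotation_about_axis <- function(u, beta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(beta) * K + (1 - cos(beta)) * (K %*% K)
}

# 3x3 complex mixing matrix in the (F+, F-, Z) basis for a spatially uniform
# rotation given in Cartesian magnetization space.
cartesian_to_epg_basis <- function(R) {
  U <- matrix(c(1, 1, 0,
                1i, -1i, 0,
                0, 0, 1), 3, 3)
  Uinv <- matrix(c(0.5, 0.5, 0,
                   -0.5i, 0.5i, 0,
                   0, 0, 1), 3, 3, byrow = TRUE)
  U %*% R %*% Uinv
}

# Effective rotation of a rectangular RF pulse, possibly off resonance.
# flip/phase in degrees, duration in ms, delta_nu in Hz. Returns the 3x3
# Cartesian rotation matrix shared by the EPG and isochromat simulators.
rf_pulse_rotation <- function(flip_deg, phase_deg = 0, pulse_ms = 0,
                              delta_nu_hz = 0) {
  alpha <- deg2rad(flip_deg)
  phi <- deg2rad(phase_deg)
  if (delta_nu_hz == 0) {
    if (alpha == 0) return(diag(3))
    return(rotation_about_axis(c(cos(phi), sin(phi), 0), alpha))
  }
  if (pulse_ms <= 0) {
    stop("off-resonant pulse requires a positive pulse duration ",
         "(effective-axis construction undefined for an instantaneous pulse)")
  }
  tau <- pulse_ms * 1e-3
  w1 <- alpha / tau
  dw <- 2 * pi * delta_nu_hz
  # off-resonance continues the free-precession sense (F+ phase -dw*t), so the
  # z-component of the effective rotation axis is -dw
  omega <- c(w1 * cos(phi), w1 * sin(phi), -dw)
  weff <- sqrt(sum(omega^2))
  if (weff == 0) return(diag(3))
  rotation_about_axis(omega / weff, weff * tau)
}

#' Apply an RF pulse to an EPG state
#'
#' Mixes every configuration order by the same 3x3 rotation. On resonance this
#' is the standard EPG rotation by (`flip_deg`, `phase_deg`). Off resonance
#' the pulse is modeled as a constant-amplitude rectangular pulse: the
#' rotation is by `sqrt(w1^2 + dw^2) * tau` about the effective axis tilted
#' out of the transverse plane, with `w1 = flip/tau` and `dw = 2*pi*delta_nu`.
#' Relaxation and diffusion are suspended during the pulse
#' (instantaneous-rotation approximation with off-resonant tilt only).
#'
#' @param state An `epg_state`.
#' @param flip_deg Nominal on-resonance flip angle in degrees.
#' @param phase_deg RF phase in degrees.
#' @param pulse_ms Pulse duration in ms. Required positive when
#'   `delta_nu_hz != 0`.
#' @param delta_nu_hz Resonance offset of the pool in Hz.
#' @return The rotated `epg_state`.
#' @export
epg_rf <- function(state, flip_deg, phase_deg = 0, pulse_ms = 0,
                   delta_nu_hz = 0) {
  T3 <- cartesian_to_epg_basis(
    rf_pulse_rotation(flip_deg, phase_deg, pulse_ms, delta_nu_hz))
  fp <- state$fp; fm <- state$fm; z <- state$z
  state$fp <- T3[1, 1] * fp + T3[1, 2] * fm + T3[1, 3] * z
  state$fm <- T3[2, 1] * fp + T3[2, 2] * fm + T3[2, 3] * z
  state$z <- T3[3, 1] * fp + T3[3, 2] * fm + T3[3, 3] * z
  state
}

#' Relaxation and recovery
#'
#' Scales all transverse amplitudes by `exp(-t/T2)` and longitudinal
#' amplitudes by `exp(-t/T1)`; the order-0 longitudinal amplitude recovers
#' toward `m0`.
#'
#' @param state An `epg_state`.
#' @param duration_ms Interval length in ms (non-negative).
#' @param t1_ms,t2_ms Relaxation times in ms.
#' @return The relaxed `epg_state`.
#' @export
epg_relax <- function(state, duration_ms, t1_ms, t2_ms) {
  if (duration_ms < 0) stop("negative relaxation duration")
  stopifnot(t1_ms > 0, t2_ms > 0)
  if (duration_ms == 0) return(state)
  e1 <- exp(-duration_ms / t1_ms)
  e2 <- exp(-duration_ms / t2_ms)
  state$fp <- state$fp * e2
  state$fm <- state$fm * e2
  state$z <- state$z * e1
  state$z[1] <- state$z[1] + state$m0 * (1 - e1)
  state
}

#' Free precession at a resonance offset
#'
#' Multiplies all F+ amplitudes by `exp(-1i * 2*pi * delta_nu * t)` and F- by
#' the conjugate factor; Z is unchanged.
#'
#' @param state An `epg_state`.
#' @param delta_nu_hz Resonance offset in Hz.
#' @param duration_ms Interval in ms.
#' @return The precessed `epg_state`.
#' @export
epg_precess <- function(state, delta_nu_hz, duration_ms) {
  if (delta_nu_hz == 0 || duration_ms == 0) return(state)
  ph <- exp(-2i * pi * delta_nu_hz * duration_ms * 1e-3)
  state$fp <- state$fp * ph
  state$fm <- state$fm * Conj(ph)
  state
}

#' Gradient dephasing shift
#'
#' Shifts F+ configuration orders up by `delta_k` and F- down, with the
#' standard conjugate hand-off through order zero. Z is unaffected. Amplitudes
#' shifted past `k_max` are dropped and their squared magnitude added to the
#' truncation-loss counter.
#'
#' @param state An `epg_state`.
#' @param delta_k Integer order change (may be negative).
#' @return The shifted `epg_state`.
#' @export
epg_shift <- function(state, delta_k) {
  dk <- as.integer(round(delta_k))
  if (abs(delta_k - dk) > 1e-9) stop("delta_k must be an integer order count")
  if (dk == 0L) return(state)
  n_old <- length(state$fp) - 1L
  # full spectrum F(o) for o = -n_old .. n_old (index o + n_old + 1)
  full <- c(Conj(rev(state$fm[-1])), state$fp)
  n_new <- min(n_old + abs(dk), state$k_max)
  if (n_old + abs(dk) > state$k_max) {
    o <- seq(-n_old, n_old)
    lost <- abs(o + dk) > state$k_max
    state$trunc_loss <- state$trunc_loss + sum(Mod(full[lost])^2)
  }
  k <- 0:n_new
  pick <- function(orders) {
    idx <- orders + n_old + 1L
    out <- complex(length(idx))
    ok <- idx >= 1L & idx <= 2L * n_old + 1L
    out[ok] <- full[idx[ok]]
    out
  }
  fp_new <- pick(k - dk)
  fm_new <- Conj(pick(-k - dk))
  state <- epg_pad(state, n_new + 1L)
  state$fp <- fp_new
  state$fm <- fm_new
  state$z <- state$z[seq_len(n_new + 1L)]
  state
}

#' Isotropic diffusion damping of configuration states
#'
#' Attenuates transverse order k by
#' `exp(-ADC * kappa^2 * (k^2 + k*delta_k + delta_k^2/3) * t)` and
#' longitudinal order k by `exp(-ADC * kappa^2 * k^2 * t)`, with
#' `kappa = 2*pi/voxel` and `delta_k` the order change produced by the
#' constant spoiler gradient during the interval. Orders are the pre-shift
#' labels: apply this operator before [epg_shift()].
#'
#' @param state An `epg_state`.
#' @param delta_k Integer order change during the interval.
#' @param interval_ms Interval length in ms (non-negative).
#' @param adc_um2_s Apparent diffusion coefficient in um^2/s (non-negative).
#' @param voxel_mm Voxel size along the spoiling direction in mm.
#' @return The attenuated `epg_state`.
#' @export
epg_diffusion <- function(state, delta_k, interval_ms, adc_um2_s, voxel_mm) {
  if (adc_um2_s < 0) stop("negative ADC")
  if (interval_ms < 0) stop("negative interval")
  if (adc_um2_s == 0 || interval_ms == 0) return(state)
  dk <- delta_k
  kappa <- 2 * pi / (voxel_mm * 1e-3)            # rad/m per order
  d <- adc_um2_s * 1e-12 * kappa^2 * interval_ms * 1e-3
  k <- seq_along(state$fp) - 1
  state$fp <- state$fp * exp(-d * (k^2 + k * dk + dk^2 / 3))
  state$fm <- state$fm * exp(-d * (k^2 - k * dk + dk^2 / 3))
  state$z <- state$z * exp(-d * k^2)
  state
}
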