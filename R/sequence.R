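# Dual-TR AFI sequence simulation to pseudo-steady state, with both the EPG
# engine and a brute-force isochromat Bloch simulator, and the arccos
# flip-angle estimator.

#' Quadratic RF-spoiling phase schedule
#'
#' The phase of the j-th pulse follows the recurrence
#' `phi_j = phi_{j-1} + j * phi0` (phase 0 before the first pulse), which has
#' the closed form `phi_j = phi0 * j * (j + 1) / 2 mod 360`.
#'
#' @param phi0_deg Phase increment in degrees.
#' @param count Number of pulses.
#' @return Numeric vector of `count` phases in degrees, reduced mod 360.
#' @examples
#' rf_phase_schedule(120, 4)  # 120 0 0 120
#' @export
rf_phase_schedule <- function(phi0_deg, count) {
  stopifnot(count >= 1)
  j <- seq_len(count)
  # triangular numbers mod 720 keep the product exact in doubles for any
  # realistic pulse count
  tri <- (j * (j + 1) / 2) %% 720
  (phi0_deg * tri) %% 360
}

# Smallest period P (in pulses) of the quadratic schedule mod 360:
# needs phi0*P = 0 and phi0*P*(P+1)/2 = 0 (mod 360). NA if none <= limit.
phase_cycle_period <- function(phi0_deg, limit = 1440L) {
  near0 <- function(x) min(x %% 360, 360 - x %% 360) < 1e-9
  for (P in seq_len(limit)) {
    if (near0(phi0_deg * P) && near0(phi0_deg * P * (P + 1) / 2)) return(P)
  }
  NA_integer_
}

# Averaging window in TR pairs: smallest multiple of the schedule's pair
# period that is >= min_pairs.
averaging_window <- function(phi0_deg, min_pairs = 32L) {
  P <- phase_cycle_period(phi0_deg)
  if (is.na(P)) return(360L)  # non-periodic increment: long fixed window
  p_pair <- if (P %% 2L == 0L) P %/% 2L else P
  as.integer(ceiling(min_pairs / p_pair) * p_pair)
}

#' Simulation settings for the AFI sequence
#'
#' @param k_max Maximum EPG dephasing order retained.
#' @param settle_pairs TR pairs simulated before signal averaging starts.
#' @param min_avg_pairs Minimum averaging window; rounded up to a whole
#'   number of RF-phase-cycle periods.
#' @param settle_tol Maximum relative change of the averaged signals between
#'   two consecutive windows for the pseudo-steady state to count as reached.
#' @param max_pairs Hard cap on simulated TR pairs before a non-convergence
#'   error.
#' @param trunc_tol Maximum tolerated truncation loss (summed squared
#'   magnitude past `k_max`) as a fraction of `m0^2`.
#' @param trim_tol Amplitude below which trailing orders are dropped from the
#'   active state (internal storage optimization; no effect above this scale).
#' @param perfect_spoiling If `TRUE`, all transverse amplitudes are zeroed
#'   immediately before each pulse (ideal-spoiling reference mode).
#' @param record `"te"` records the demodulated signal at the echo time;
#'   `"pulse"` records it directly after the pulse with the T2 decay to TE
#'   applied but without the pulse-to-TE precession phase (the convention used
#'   for the off-resonant pool of the two-frequency model, where the
#'   interference combination supplies that phase explicitly).
#' @return A list of settings for [simulate_afi()].
#' @export
afi_settings <- function(k_max = 4096, settle_pairs = 200L,
                         min_avg_pairs = 32L, settle_tol = 1e-6,
                         max_pairs = 2000L, trunc_tol = 1e-6,
                         trim_tol = 1e-16, perfect_spoiling = FALSE,
                         record = c("te", "pulse")) {
  list(k_max = k_max, settle_pairs = as.integer(settle_pairs),
       min_avg_pairs = as.integer(min_avg_pairs), settle_tol = settle_tol,
       max_pairs = as.integer(max_pairs), trunc_tol = trunc_tol,
       trim_tol = trim_tol, perfect_spoiling = isTRUE(perfect_spoiling),
       record = match.arg(record))
}

afi_signals <- function(s1, s2, n_pairs, residual, trunc_loss = 0) {
  structure(list(s1 = s1, s2 = s2,
                 settle_report = list(n_pairs = n_pairs, residual = residual,
                                      trunc_loss = trunc_loss)),
            class = "afi_signals")
}

#' @export
print.afi_signals <- function(x, ...) {
  cat(sprintf("<afi_signals> |S1| = %.6g, |S2| = %.6g (r = %.5f)\n",
              Mod(x$s1), Mod(x$s2), Mod(x$s2) / Mod(x$s1)))
  cat(sprintf("  pairs simulated = %d, settle residual = %.3g, truncation loss = %.3g\n",
              x$settle_report$n_pairs, x$settle_report$residual,
              x$settle_report$trunc_loss))
  invisible(x)
}

#' Simulate the AFI sequence with the EPG engine
#'
#' Alternates TR1/TR2 intervals of the dual-TR AFI sequence to pseudo-steady
#' state. Each interval applies the scheduled RF pulse, relaxes and precesses
#' to the echo time where the demodulated complex signal is recorded, then
#' plays the spoiler (diffusion damping followed by the gradient order shift)
#' together with relaxation and precession over the remainder of the TR. After
#' a settling phase the demodulated signals are averaged over whole
#' RF-phase-cycle periods; the run is extended until two consecutive windows
#' agree to `settle_tol`.
#'
#' @param protocol An [afi_protocol()].
#' @param tissue A [tissue_component()].
#' @param settings An [afi_settings()] list.
#' @return An `afi_signals` object with complex `s1`, `s2` and a
#'   `settle_report`.
#' @examples
#' \donttest{
#' p <- afi_protocol(phi0_deg = 120)
#' w1 <- tissue_component(1301, 585, 1930)
#' sig <- simulate_afi(p, w1)
#' afi_flip_angle(sig, p$n)
#' }
#' @export
simulate_afi <- function(protocol, tissue, settings = afi_settings()) {
  stopifnot(inherits(protocol, "afi_protocol"),
            inherits(tissue, "tissue_component"))
  st <- epg_state(k_max = settings$k_max)
  drive <- function(state, n_pairs, record_fun) {
    run_afi_intervals(state, protocol, tissue, settings, n_pairs, record_fun)
  }
  run_afi_pseudo_steady(protocol, settings, drive)
}

# Shared pseudo-steady-state driver: `drive(state, n_pairs, collect)` advances
# the simulator by n_pairs TR pairs, appending demodulated (s1, s2) samples.
run_afi_pseudo_steady <- function(protocol, settings, drive) {
  W <- averaging_window(protocol$phi0_deg, settings$min_avg_pairs)
  env <- new.env(parent = emptyenv())
  env$s1 <- complex(0); env$s2 <- complex(0)
  collect <- function(s1, s2) {
    env$s1 <- c(env$s1, s1); env$s2 <- c(env$s2, s2)
  }
  state <- drive(NULL, settings$settle_pairs, NULL)
  total <- settings$settle_pairs
  prev <- NULL
  resid <- NA_real_
  repeat {
    state <- drive(state, W, collect)
    total <- total + W
    n <- length(env$s1)
    cur <- c(mean(env$s1[(n - W + 1):n]), mean(env$s2[(n - W + 1):n]))
    if (!is.null(prev)) {
      resid <- max(Mod(cur - prev) / pmax(Mod(cur), 1e-300))
      if (resid < settings$settle_tol) {
        return(afi_signals(cur[1], cur[2], total, resid,
                           attr(state, "trunc_loss")))
      }
    }
    prev <- cur
    if (total + W > settings$max_pairs) {
      stop(sprintf(
        "AFI simulation did not reach pseudo-steady state within %d TR pairs (last residual %.3g)",
        total, resid))
    }
  }
}

# Advance the EPG state by n_pairs TR pairs. `state` NULL means start from
# equilibrium. Returns the state with attr trunc_loss.
run_afi_intervals <- function(state, protocol, tissue, settings, n_pairs,
                              collect) {
  p <- protocol
  if (is.null(state)) {
    st <- epg_state(k_max = settings$k_max)
    j0 <- 0L
  } else {
    st <- state$st
    j0 <- state$j0
  }
  phases <- rf_phase_schedule(p$phi0_deg, j0 + 2L * n_pairs)
  rem1 <- p$tr1_ms - p$te_ms
  rem2 <- p$tr2_ms - p$te_ms
  dnu <- tissue$delta_nu_hz
  # pulse mixing matrices repeat with the phase-cycle period, so cache them
  mat_cache <- new.env(parent = emptyenv())
  pulse_matrix <- function(phase) {
    key <- sprintf("%.9f", phase)
    m <- mat_cache[[key]]
    if (is.null(m)) {
      m <- cartesian_to_epg_basis(
        rf_pulse_rotation(p$alpha_deg, phase, p$pulse_ms, dnu))
      mat_cache[[key]] <- m
    }
    m
  }
  ph_te <- exp(-2i * pi * dnu * p$te_ms * 1e-3)
  unphase_te <- if (settings$record == "pulse") Conj(ph_te) else 1 + 0i
  for (pair in seq_len(n_pairs)) {
    for (half in 1:2) {
      j <- j0 + 2L * (pair - 1L) + half
      phase <- phases[j]
      if (settings$perfect_spoiling) {
        st$fp[] <- 0i; st$fm[] <- 0i
        st <- epg_trim(st, settings$trim_tol)
      }
      T3 <- pulse_matrix(phase)
      fp <- st$fp; fm <- st$fm; z <- st$z
      st$fp <- T3[1, 1] * fp + T3[1, 2] * fm + T3[1, 3] * z
      st$fm <- T3[2, 1] * fp + T3[2, 2] * fm + T3[2, 3] * z
      st$z <- T3[3, 1] * fp + T3[3, 2] * fm + T3[3, 3] * z
      st <- epg_relax(st, p$te_ms, tissue$t1_ms, tissue$t2_ms)
      st <- epg_precess(st, dnu, p$te_ms)
      if (!is.null(collect)) {
        sig <- st$fp[1] * exp(-1i * deg2rad(phase)) * unphase_te
        if (half == 1L) collect(sig, NULL) else collect(NULL, sig)
      }
      rem <- if (half == 1L) rem1 else rem2
      dk <- if (half == 1L) p$dk1 else p$dk2
      st <- epg_diffusion(st, dk, rem, tissue$adc_um2_s, p$voxel_mm)
      st <- epg_shift(st, dk)
      st <- epg_relax(st, rem, tissue$t1_ms, tissue$t2_ms)
      st <- epg_precess(st, dnu, rem)
    }
    st <- epg_trim(st, settings$trim_tol)
    if (st$trunc_loss > settings$trunc_tol * st$m0^2) {
      stop(sprintf(
        "EPG truncation loss %.3g exceeds tolerance %.3g of m0^2; increase k_max",
        st$trunc_loss, settings$trunc_tol))
    }
  }
  out <- list(st = st, j0 = j0 + 2L * n_pairs)
  attr(out, "trunc_loss") <- st$trunc_loss
  out
}

#' Simulate the AFI sequence with a brute-force isochromat ensemble
#'
#' Independent cross-check of [simulate_afi()]: `n_spins` isochromats
#' uniformly span one voxel, each accruing the spoiler dephasing
#' `2*pi*orders*x` at its position x, with identical RF phases, relaxation,
#' off-resonant precession and signal averaging. Diffusion is not represented
#' (use `adc_um2_s = 0` pools for quantitative comparison against the EPG
#' engine).
#'
#' @inheritParams simulate_afi
#' @param n_spins Number of isochromats (>= 500 recommended for quantitative
#'   use).
#' @return An `afi_signals` object.
#' @export
simulate_afi_isochromat <- function(protocol, tissue, n_spins = 2000,
                                    settings = afi_settings()) {
  stopifnot(inherits(protocol, "afi_protocol"),
            inherits(tissue, "tissue_component"), n_spins >= 2)
  p <- protocol
  dnu <- tissue$delta_nu_hz
  x <- ((seq_len(n_spins) - 0.5) / n_spins) - 0.5  # voxel fractions
  spoil1 <- exp(2i * pi * p$dk1 * x)
  spoil2 <- exp(2i * pi * p$dk2 * x)
  rem1 <- p$tr1_ms - p$te_ms
  rem2 <- p$tr2_ms - p$te_ms
  e1te <- exp(-p$te_ms / tissue$t1_ms); e2te <- exp(-p$te_ms / tissue$t2_ms)
  e1r <- exp(-c(rem1, rem2) / tissue$t1_ms)
  e2r <- exp(-c(rem1, rem2) / tissue$t2_ms)
  ph_te <- exp(-2i * pi * dnu * p$te_ms * 1e-3)
  ph_rem <- exp(-2i * pi * dnu * c(rem1, rem2) * 1e-3)
  unphase_te <- if (settings$record == "pulse") Conj(ph_te) else 1 + 0i
  mat_cache <- new.env(parent = emptyenv())
  pulse_matrix <- function(phase) {
    key <- sprintf("%.9f", phase)
    m <- mat_cache[[key]]
    if (is.null(m)) {
      m <- rf_pulse_rotation(p$alpha_deg, phase, p$pulse_ms, dnu)
      mat_cache[[key]] <- m
    }
    m
  }
  drive <- function(state, n_pairs, collect) {
    if (is.null(state)) {
      mxy <- complex(n_spins)
      mz <- rep(1, n_spins)
      j0 <- 0L
    } else {
      mxy <- state$mxy; mz <- state$mz; j0 <- state$j0
    }
    phases <- rf_phase_schedule(p$phi0_deg, j0 + 2L * n_pairs)
    for (pair in seq_len(n_pairs)) {
      for (half in 1:2) {
        j <- j0 + 2L * (pair - 1L) + half
        phase <- phases[j]
        if (settings$perfect_spoiling) mxy[] <- 0i
        R <- pulse_matrix(phase)
        mx <- Re(mxy); my <- Im(mxy)
        nx <- R[1, 1] * mx + R[1, 2] * my + R[1, 3] * mz
        ny <- R[2, 1] * mx + R[2, 2] * my + R[2, 3] * mz
        mz <- R[3, 1] * mx + R[3, 2] * my + R[3, 3] * mz
        mxy <- complex(real = nx, imaginary = ny)
        mxy <- mxy * (e2te * ph_te)
        mz <- mz * e1te + (1 - e1te)
        if (!is.null(collect)) {
          sig <- mean(mxy) * exp(-1i * deg2rad(phase)) * unphase_te
          if (half == 1L) collect(sig, NULL) else collect(NULL, sig)
        }
        spoil <- if (half == 1L) spoil1 else spoil2
        mxy <- mxy * spoil * (e2r[half] * ph_rem[half])
        mz <- mz * e1r[half] + (1 - e1r[half])
      }
    }
    out <- list(mxy = mxy, mz = mz, j0 = j0 + 2L * n_pairs)
    attr(out, "trunc_loss") <- 0
    out
  }
  run_afi_pseudo_steady(p, settings, drive)
}

#' Estimate the flip angle from the dual-TR signal pair
#'
#' The AFI estimator: with `r = |S2|/|S1|` and `n = TR2/TR1`,
#' `alpha = arccos((r*n - 1)/(n - r))` in degrees. When the arccos argument
#' falls outside `[-1, 1]` (possible for interfering or noisy signals) the
#' estimate is the distinguished failed value `NA_real_`, not an error.
#'
#' @param signals An `afi_signals` object, or a complex/numeric vector `s1`.
#' @param n TR ratio `tr2/tr1`.
#' @param s2 Second signal when `signals` is given as `s1` directly.
#' @return Flip angle in degrees, or `NA_real_` when estimation failed.
#' @examples
#' afi_flip_angle(1, 5, 7 / 11)  # 60 degrees
#' afi_flip_angle(1, 5, 1.2)     # NA: arccos argument out of range
#' @export
afi_flip_angle <- function(signals, n, s2 = NULL) {
  if (inherits(signals, "afi_signals")) {
    s1 <- signals$s1
    s2 <- signals$s2
  } else {
    s1 <- signals
    if (is.null(s2)) stop("s2 required when signals are given as vectors")
  }
  if (any(Mod(s1) == 0)) stop("zero |s1|: flip-angle estimator undefined")
  r <- Mod(s2) / Mod(s1)
  if (any(abs(r - n) < 1e-12)) stop("r equals n: estimator degenerate")
  arg <- (r * n - 1) / (n - r)
  out <- rep(NA_real_, length(arg))
  ok <- arg >= -1 & arg <= 1
  out[ok] <- rad2deg(acos(arg[ok]))
  out
}
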