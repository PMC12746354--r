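# Two-frequency signal-interference model: a resonant water pool plus one
# off-resonant PVP band, combined as
#   S_i = S_i,res + w * S_i,off * exp(-1i * (2*pi*dnu*TE + phi)),  i = 1, 2.
# The off-pool signal is recorded at the pulse (T2 decay to TE applied, no
# in-state pulse-to-TE precession phase); the combination factor supplies all
# pulse-to-readout phase, so nothing is double counted. The factor's sign
# matches this package's transverse chirality (F+ = Mx + i*My accumulates
# phase -2*pi*dnu*t, see epg_precess): the pulse-to-readout phase it supplies
# is the continued in-state phase. Reported (w, phi) values from the
# conjugate-frame convention drop in unchanged.

#' Interference parameters of the two-frequency model
#'
#' @param w Dimensionless weight of the off-resonant component (>= 0).
#' @param phi Phase offset in radians; wrapped to (-pi, pi]. Give either
#'   `phi` or `phi_pi`.
#' @param phi_pi Phase offset in units of pi (the interchange convention for
#'   reported values, e.g. -0.18 for -0.18*pi).
#' @param delta_nu_hz Resonance offset of the off component in Hz.
#' @return An object of class `interference_params`.
#' @examples
#' interference_params(w = 0.136, phi_pi = -0.18, delta_nu_hz = 320)
#' @export
interference_params <- function(w, phi = NULL, phi_pi = NULL,
                                delta_nu_hz = 320) {
  stopifnot(w >= 0)
  if (is.null(phi) == is.null(phi_pi)) {
    stop("give exactly one of phi (radians) or phi_pi (units of pi)")
  }
  if (is.null(phi)) phi <- phi_pi * pi
  structure(list(w = w, phi = wrap_pi(phi), delta_nu_hz = delta_nu_hz),
            class = "interference_params")
}

#' @export
print.interference_params <- function(x, ...) {
  cat(sprintf("<interference_params> w = %.4g, phi = %.4g*pi, dnu = %g Hz\n",
              x$w, x$phi / pi, x$delta_nu_hz))
  invisible(x)
}

#' Two-component phantom system
#'
#' The resonant water pool plus one off-resonant PVP pool. Both pools share
#' the same ADC (the off-resonant protons experience the same voxel-level
#' diffusion weighting in the model).
#'
#' @param res [tissue_component()] with `delta_nu_hz = 0`.
#' @param off [tissue_component()] with a non-zero `delta_nu_hz`.
#' @return An object of class `two_component_system`.
#' @examples
#' sys <- two_component_system(
#'   res = tissue_component(1292, 780, 990),
#'   off = tissue_component(100, 5.7, 990, delta_nu_hz = 320))
#' @export
two_component_system <- function(res, off) {
  stopifnot(inherits(res, "tissue_component"),
            inherits(off, "tissue_component"))
  if (res$delta_nu_hz != 0) stop("res pool must have delta_nu_hz = 0")
  if (off$delta_nu_hz == 0) stop("off pool must have delta_nu_hz != 0")
  if (res$adc_um2_s != off$adc_um2_s) {
    stop("both pools must share the same ADC")
  }
  structure(list(res = res, off = off), class = "two_component_system")
}

#' @export
print.two_component_system <- function(x, ...) {
  cat("<two_component_system>\n  res: "); print(x$res)
  cat("  off: "); print(x$off)
  invisible(x)
}

#' Off-resonant PVP pool defaults
#'
#' Relaxation defaults for the off-resonant PVP proton pool, from
#' inversion-recovery T1 of the PVP resonances and the T2* of the
#' upfield-shifted band: T1 = 100 ms / T2 = 5.7 ms for weight fractions up to
#' 25 wt%, T1 = 70 ms / T2 = 1.6 ms at 50 wt% (linear interpolation of T1 and
#' log-linear interpolation of T2 in between).
#'
#' @param pvp_wt_percent PVP weight fraction in percent.
#' @param adc_um2_s ADC shared with the water pool, um^2/s.
#' @param delta_nu_hz Resonance offset in Hz (320 at 3 T, 747 at 7 T).
#' @return A [tissue_component()] for the off-resonant pool.
#' @export
pvp_off_pool <- function(pvp_wt_percent, adc_um2_s, delta_nu_hz = 320) {
  stopifnot(pvp_wt_percent >= 0)
  if (pvp_wt_percent <= 25) {
    t1 <- 100; t2 <- 5.7
  } else if (pvp_wt_percent >= 50) {
    t1 <- 70; t2 <- 1.6
  } else {
    f <- (pvp_wt_percent - 25) / 25
    t1 <- 100 + f * (70 - 100)
    t2 <- exp(log(5.7) + f * (log(1.6) - log(5.7)))
  }
  tissue_component(t1, t2, adc_um2_s, delta_nu_hz)
}

#' Combine resonant and off-resonant signals
#'
#' The two-frequency interference combination
#' `s_res + w * s_off * exp(-1i * (2*pi*delta_nu*te + phi))`. The
#' exponential accounts for the phase the off-resonant component accumulates
#' in the rotating frame between excitation and readout; its sign follows the
#' package's transverse phase convention (see [epg_precess()]), under which
#' the off pool accumulates `-2*pi*delta_nu*te` during TE.
#'
#' @param s_res,s_off Complex signals of the resonant and off-resonant pools
#'   (the off signal recorded at the pulse with T2 decay to TE applied).
#' @param params An [interference_params()].
#' @param te_ms Echo time in ms.
#' @return Complex combined signal (vectorized over the signal arguments).
#' @export
combine_signals <- function(s_res, s_off, params, te_ms) {
  stopifnot(inherits(params, "interference_params"))
  fac <- exp(-1i * (2 * pi * params$delta_nu_hz * te_ms * 1e-3 + params$phi))
  s_res + params$w * s_off * fac
}

#' Simulate per-pool AFI component signals over a phi0 grid
#'
#' Runs the EPG simulator once per pool and grid point and returns the raw
#' complex component signals. The resonant pool is recorded at TE; the
#' off-resonant pool at the pulse (see [afi_settings()] `record`). These
#' signals do not depend on the interference parameters `(w, phi)`, so a
#' single component table supports arbitrarily many combinations via
#' [combine_components()] — this is what makes interference fitting cheap.
#'
#' @param protocol An [afi_protocol()]; its `phi0_deg` is overridden by the
#'   grid.
#' @param system A [two_component_system()].
#' @param phi0 Numeric vector of RF-spoiling increments in degrees.
#' @param settings An [afi_settings()] list.
#' @return An object of class `afi_components`: a data frame with columns
#'   `phi0_deg`, `s1_res`, `s2_res`, `s1_off`, `s2_off` (complex), carrying
#'   the protocol and system as attributes.
#' @export
simulate_components <- function(protocol, system, phi0 = seq(0, 180, by = 20),
                                settings = afi_settings()) {
  stopifnot(inherits(system, "two_component_system"))
  res_set <- settings; res_set$record <- "te"
  off_set <- settings; off_set$record <- "pulse"
  rows <- lapply(phi0, function(p0) {
    prot <- protocol; prot$phi0_deg <- p0
    sr <- simulate_afi(prot, system$res, res_set)
    so <- simulate_afi(prot, system$off, off_set)
    data.frame(phi0_deg = p0,
               s1_res = sr$s1, s2_res = sr$s2,
               s1_off = so$s1, s2_off = so$s2)
  })
  out <- do.call(rbind, rows)
  attr(out, "protocol") <- protocol
  attr(out, "system") <- system
  class(out) <- c("afi_components", "data.frame")
  out
}

#' Combine component signals into flip-angle estimates
#'
#' Applies the two-frequency combination to a component table and estimates
#' the flip angle at every grid point.
#'
#' @param components An `afi_components` table from [simulate_components()].
#' @param params An [interference_params()].
#' @param te_ms Echo time used in the combination phase; defaults to the
#'   protocol's TE (the TE the components were simulated at).
#' @return A data frame with columns `phi0_deg`, `s1`, `s2` (complex
#'   combined signals) and `alpha_deg` (NA where estimation failed).
#' @export
combine_components <- function(components, params, te_ms = NULL) {
  prot <- attr(components, "protocol")
  if (is.null(te_ms)) te_ms <- prot$te_ms
  s1 <- combine_signals(components$s1_res, components$s1_off, params, te_ms)
  s2 <- combine_signals(components$s2_res, components$s2_off, params, te_ms)
  data.frame(phi0_deg = components$phi0_deg, s1 = s1, s2 = s2,
             alpha_deg = afi_flip_angle(s1, prot$n, s2))
}

#' Simulate one two-frequency AFI acquisition
#'
#' Runs the EPG simulator once per pool at the protocol's `phi0_deg` and
#' combines the signals via [combine_signals()].
#'
#' @inheritParams simulate_components
#' @param params An [interference_params()].
#' @return An `afi_signals` object with the combined complex `s1`, `s2`.
#' @export
simulate_afi_two_component <- function(protocol, system, params,
                                       settings = afi_settings()) {
  comp <- simulate_components(protocol, system, phi0 = protocol$phi0_deg,
                              settings = settings)
  cmb <- combine_components(comp, params)
  afi_signals(cmb$s1[1], cmb$s2[1], NA_integer_, NA_real_)
}
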