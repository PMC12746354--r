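# Domain types: magnetization pools and the AFI acquisition protocol.

#' Define a magnetization pool
#'
#' One tissue/resonance component with its relaxation, diffusion and
#' off-resonance parameters.
#'
#' @param t1_ms,t2_ms Longitudinal/transverse relaxation times in ms.
#' @param adc_um2_s Apparent diffusion coefficient in um^2/s.
#' @param delta_nu_hz Resonance offset in Hz (0 for the on-resonant water
#'   pool).
#' @return An object of class `tissue_component`.
#' @examples
#' w1_3t <- tissue_component(t1_ms = 1301, t2_ms = 585, adc_um2_s = 1930)
#' @export
tissue_component <- function(t1_ms, t2_ms, adc_um2_s = 0, delta_nu_hz = 0) {
  stopifnot(t1_ms > 0, t2_ms > 0, adc_um2_s >= 0)
  if (t2_ms > t1_ms) {
    warning("t2_ms > t1_ms is physically unusual; proceeding")
  }
  structure(
    list(t1_ms = t1_ms, t2_ms = t2_ms, adc_um2_s = adc_um2_s,
         delta_nu_hz = delta_nu_hz),
    class = "tissue_component"
  )
}

#' @export
print.tissue_component <- function(x, ...) {
  cat(sprintf(
    "<tissue_component> T1 = %g ms, T2 = %g ms, ADC = %g um^2/s, dnu = %g Hz\n",
    x$t1_ms, x$t2_ms, x$adc_um2_s, x$delta_nu_hz))
  invisible(x)
}

#' Define an AFI acquisition protocol
#'
#' Sequence parameters for the dual-TR AFI acquisition: two interleaved
#' repetition times TR1 < TR2 with identical pulses, quadratic RF phase
#' cycling with increment `phi0_deg`, and spoiler gradient moments `a_g1` /
#' `a_g2` applied in the TR1 / TR2 intervals. Moments must be (within 0.5%)
#' integer multiples of the 2*pi dephasing quantum for the voxel.
#'
#' @param tr1_ms,tr2_ms Repetition times in ms; `tr2_ms/tr1_ms` must be an
#'   integer (the AFI ratio n).
#' @param te_ms Echo time in ms; must satisfy `te_ms < tr1_ms`.
#' @param alpha_deg Flip angle of the excitation pulses in degrees (the true
#'   angle played out; also the nominal angle of the protocol).
#' @param phi0_deg RF-spoiling phase increment in degrees.
#' @param a_g1,a_g2 Spoiler gradient moments in mT*ms/m for the TR1 and TR2
#'   intervals.
#' @param pulse_ms Rectangular pulse duration in ms.
#' @param voxel_mm Voxel size along the spoiling direction in mm.
#' @return An object of class `afi_protocol` with the derived integer ratio
#'   `n` and spoiler order counts `dk1`, `dk2`.
#' @examples
#' p <- afi_protocol(phi0_deg = 120)  # the default 3 T protocol, moment set I
#' p$n    # 5
#' p$dk1  # 10 (20*pi over the 2 mm voxel)
#' @export
afi_protocol <- function(tr1_ms = 25, tr2_ms = 125, te_ms = 1.9,
                         alpha_deg = 60, phi0_deg = 120,
                         a_g1 = 117.5, a_g2 = 587.5,
                         pulse_ms = 0.5, voxel_mm = 2.0) {
  stopifnot(tr1_ms > 0, tr2_ms > tr1_ms, te_ms > 0, pulse_ms >= 0,
            voxel_mm > 0, a_g1 >= 0, a_g2 >= 0)
  if (te_ms >= tr1_ms) stop("te_ms must be smaller than tr1_ms")
  n <- tr2_ms / tr1_ms
  if (abs(n - round(n)) > 1e-9) {
    stop("tr2_ms/tr1_ms must be an integer ratio")
  }
  structure(
    list(tr1_ms = tr1_ms, tr2_ms = tr2_ms, te_ms = te_ms,
         alpha_deg = alpha_deg, phi0_deg = phi0_deg,
         a_g1 = a_g1, a_g2 = a_g2, pulse_ms = pulse_ms, voxel_mm = voxel_mm,
         n = as.integer(round(n)),
         dk1 = moment_to_orders(a_g1, voxel_mm),
         dk2 = moment_to_orders(a_g2, voxel_mm)),
    class = "afi_protocol"
  )
}

#' @export
print.afi_protocol <- function(x, ...) {
  cat(sprintf(
    paste0("<afi_protocol> TR1/TR2 = %g/%g ms (n = %d), TE = %g ms, ",
           "alpha = %g deg\n  phi0 = %g deg, A_G1/A_G2 = %g/%g mT*ms/m ",
           "(%d/%d cycles over %g mm), pulse %g ms\n"),
    x$tr1_ms, x$tr2_ms, x$n, x$te_ms, x$alpha_deg, x$phi0_deg,
    x$a_g1, x$a_g2, x$dk1, x$dk2, x$voxel_mm, x$pulse_ms))
  invisible(x)
}

#' Spoiler gradient moment sets
#'
#' The four named spoiler moment settings used for spoiling-curve and TE-sweep
#' acquisitions, as A_G1/A_G2 pairs in mT*ms/m: I = 117.5/587.5,
#' II = 234.9/1174.5, III = 469.7/2348.5, IV = 705/3525. Over a 2.0 mm voxel
#' these correspond to 20*pi/100*pi, 40*pi/200*pi, 80*pi/400*pi and
#' 120*pi/600*pi dephasing.
#'
#' @return Named list of length-2 numeric vectors `c(a_g1, a_g2)`.
#' @export
moment_sets <- function() {
  list(I = c(117.5, 587.5),
       II = c(234.9, 1174.5),
       III = c(469.7, 2348.5),
       IV = c(705, 3525))
}

#' Convert a spoiler gradient moment to integer dephasing orders
#'
#' A moment A (mT*ms/m) applied over a voxel of size L produces
#' `gamma * A * L` cycles (i.e. `2 * gamma * A * L` multiples of pi) of
#' dephasing across the voxel. Moments must be quantized to the 2*pi quantum
#' `1/(gamma*L)` within 0.5%.
#'
#' @param moment Spoiler gradient moment in mT*ms/m.
#' @param voxel_mm Voxel size in mm.
#' @return Integer number of 2*pi cycles, with attribute `pi_multiples`
#'   giving the exact dephasing in multiples of pi.
#' @examples
#' moment_to_orders(117.5, 2.0)  # 10 cycles = 20*pi
#' moment_to_orders(11.75, 2.0)  # 1 cycle = 2*pi
#' @export
moment_to_orders <- function(moment, voxel_mm) {
  stopifnot(moment >= 0, voxel_mm > 0)
  cycles <- gyromagnetic_ratio() * (moment * 1e-6) * (voxel_mm * 1e-3)
  k <- round(cycles)
  if (cycles > 0 && abs(cycles - k) > 0.005 * max(k, 1)) {
    quantum <- 1 / (gyromagnetic_ratio() * voxel_mm * 1e-3) * 1e6
    stop(sprintf(
      "moment %g mT*ms/m is not a 2*pi multiple over %g mm; nearest valid value is %.4g mT*ms/m",
      moment, voxel_mm, k * quantum))
  }
  structure(as.integer(k), pi_multiples = 2 * cycles)
}
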