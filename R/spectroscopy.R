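# Closed-form conversions connecting NMR spectroscopy observables to
# simulation inputs.

#' Convert a chemical shift to Hz
#'
#' `shift_ppm * gamma/2pi * B0 * 1e-6`.
#'
#' @param shift_ppm Chemical shift (or shift difference) in ppm.
#' @param field_t Static field strength in T.
#' @return Frequency in Hz.
#' @examples
#' ppm_to_hz(1, 1.88)  # ~ 80 Hz
#' @export
ppm_to_hz <- function(shift_ppm, field_t) {
  stopifnot(field_t > 0)
  shift_ppm * gyromagnetic_ratio() * field_t * 1e-6
}

#' T2* from a Lorentzian line width
#'
#' For a Lorentzian line, `T2* = 1 / (pi * FWHM_Hz)`.
#'
#' @param fwhm_ppm Full width at half maximum in ppm (> 0).
#' @param field_t Static field strength in T.
#' @return T2* in ms.
#' @examples
#' t2star_from_fwhm(0.7, 1.88)  # ~ 5.7 ms
#' t2star_from_fwhm(2.5, 1.88)  # ~ 1.6 ms
#' @export
t2star_from_fwhm <- function(fwhm_ppm, field_t) {
  if (any(fwhm_ppm <= 0)) stop("fwhm_ppm must be positive")
  1000 / (pi * ppm_to_hz(fwhm_ppm, field_t))
}

#' T1 from the inversion-recovery zero crossing
#'
#' With `Mz(t) = 1 - 2*exp(-t/T1)`, the signal vanishes at `t0 = T1 * ln 2`,
#' so `T1 = t0 / ln 2`.
#'
#' @param t0_ms Zero-crossing recovery delay in ms (> 0).
#' @return T1 in ms.
#' @examples
#' t1_from_zero_crossing(69.31)  # ~ 100 ms
#' @export
t1_from_zero_crossing <- function(t0_ms) {
  if (any(t0_ms <= 0)) stop("t0_ms must be positive")
  t0_ms / log(2)
}

#' Spectral band description
#'
#' @param center_ppm Band center in ppm.
#' @param fwhm_ppm Full width at half maximum in ppm (> 0).
#' @param assignment Free-text label.
#' @return A one-row data frame of class `spectral_band`.
#' @export
spectral_band <- function(center_ppm, fwhm_ppm, assignment = "") {
  if (any(fwhm_ppm <= 0)) stop("fwhm_ppm must be positive")
  out <- data.frame(center_ppm = center_ppm, fwhm_ppm = fwhm_ppm,
                    assignment = assignment)
  class(out) <- c("spectral_band", "data.frame")
  out
}

#' Read a spectral band table from CSV
#'
#' Columns: `center_ppm`, `fwhm_ppm`, `label`.
#'
#' @param path CSV file path.
#' @return A `spectral_band` data frame.
#' @export
read_band_table <- function(path) {
  d <- utils::read.csv(path)
  spectral_band(d$center_ppm, d$fwhm_ppm,
                if ("label" %in% names(d)) d$label else "")
}
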