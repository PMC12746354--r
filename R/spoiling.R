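# Spoiling curves (flip angle vs RF-spoiling increment) and TE sweeps, with
# the summary statistics used to characterize them: the 60/120-degree
# asymmetry, the grid minimum and the percent deviation from a reference.

#' Construct a spoiling curve
#'
#' A flip-angle estimate per RF-spoiling increment. Failed estimates (arccos
#' argument out of range) are first-class values: `alpha_deg` is `NA` and
#' `failed` is `TRUE`; statistics skip them but report their count.
#'
#' @param phi0_deg Strictly increasing grid of spoiling increments (degrees).
#' @param alpha_deg Flip-angle estimates (degrees, `NA` = failed).
#' @param alpha_sd_deg Standard deviations (degrees, 0 for noiseless
#'   simulation).
#' @param failed Logical failure markers; defaults to `is.na(alpha_deg)`.
#' @param reference_alpha Reference flip angle in degrees.
#' @param provenance One of `"simulated"`, `"synthetic-measured"`, `"file"`.
#' @return An object of class `spoiling_curve` (a data frame with attributes
#'   `reference_alpha` and `provenance`).
#' @export
spoiling_curve <- function(phi0_deg, alpha_deg, alpha_sd_deg = 0,
                           failed = is.na(alpha_deg), reference_alpha = NA,
                           provenance = "simulated") {
  if (length(phi0_deg) < 1 || any(diff(phi0_deg) <= 0)) {
    stop("phi0_deg grid must be non-empty and strictly increasing")
  }
  if (any(alpha_sd_deg < 0, na.rm = TRUE)) stop("alpha_sd_deg must be >= 0")
  out <- data.frame(phi0_deg = phi0_deg, alpha_deg = alpha_deg,
                    alpha_sd_deg = rep_len(alpha_sd_deg, length(phi0_deg)),
                    failed = rep_len(failed, length(phi0_deg)))
  attr(out, "reference_alpha") <- reference_alpha
  attr(out, "provenance") <- provenance
  class(out) <- c("spoiling_curve", "data.frame")
  out
}

#' @export
print.spoiling_curve <- function(x, ...) {
  cat(sprintf("<spoiling_curve> %d points (%s), %d failed, reference = %s deg\n",
              nrow(x), attr(x, "provenance"), sum(x$failed),
              format(attr(x, "reference_alpha"))))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
plot.spoiling_curve <- function(x, ..., add = FALSE, col = 1, pch = 16) {
  if (!add) {
    plot(x$phi0_deg, x$alpha_deg, xlab = expression(Phi[0] ~ "(deg)"),
         ylab = expression(alpha ~ "(deg)"), col = col, pch = pch, ...)
  } else {
    points(x$phi0_deg, x$alpha_deg, col = col, pch = pch, ...)
  }
  ok <- !x$failed & x$alpha_sd_deg > 0
  if (any(ok)) {
    arrows(x$phi0_deg[ok], x$alpha_deg[ok] - x$alpha_sd_deg[ok],
           x$phi0_deg[ok], x$alpha_deg[ok] + x$alpha_sd_deg[ok],
           angle = 90, code = 3, length = 0.03, col = col)
  }
  ref <- attr(x, "reference_alpha")
  if (is.finite(ref)) abline(h = ref, lty = 2, col = "grey40")
  invisible(x)
}

#' Simulate a spoiling curve
#'
#' Sweeps the RF-spoiling increment at fixed other protocol parameters and
#' estimates the flip angle at each grid point, with either the
#' single-frequency EPG simulator (a `tissue_component`) or the two-frequency
#' interference model (a `two_component_system` plus `params`).
#'
#' @param protocol An [afi_protocol()] template; `phi0_deg` is swept.
#' @param component A [tissue_component()] or a [two_component_system()].
#' @param phi0 Grid of spoiling increments in degrees.
#' @param params [interference_params()], required for a two-component system.
#' @param settings An [afi_settings()] list.
#' @param reference_alpha Reference flip angle (defaults to the protocol's
#'   flip angle, the value a perfect measurement would return).
#' @return A [spoiling_curve()].
#' @examples
#' \donttest{
#' p <- afi_protocol()
#' crv <- simulate_spoiling_curve(p, tissue_component(1301, 585, 1930))
#' asymmetry(crv)
#' }
#' @export
simulate_spoiling_curve <- function(protocol, component,
                                    phi0 = seq(0, 180, by = 20),
                                    params = NULL,
                                    settings = afi_settings(),
                                    reference_alpha = protocol$alpha_deg) {
  stopifnot(all(diff(phi0) > 0))
  if (inherits(component, "two_component_system")) {
    if (is.null(params)) stop("params required for a two-component system")
    comp <- simulate_components(protocol, component, phi0, settings)
    alpha <- combine_components(comp, params)$alpha_deg
  } else if (inherits(component, "tissue_component")) {
    alpha <- vapply(phi0, function(p0) {
      prot <- protocol; prot$phi0_deg <- p0
      afi_flip_angle(simulate_afi(prot, component, settings), prot$n)
    }, numeric(1))
  } else {
    stop("component must be a tissue_component or two_component_system")
  }
  spoiling_curve(phi0, alpha, alpha_sd_deg = 0,
                 reference_alpha = reference_alpha, provenance = "simulated")
}

#' Spoiling-curve asymmetry
#'
#' The signed difference `alpha(120 deg) - alpha(60 deg)` between the two
#' candidate minimum locations, zero for a curve symmetric about 90 degrees.
#' Negative values indicate a minimum shifted from 60 to 120 degrees.
#'
#' @param curve A [spoiling_curve()].
#' @return Signed asymmetry in degrees, or `NA_real_` when either grid point
#'   is absent or failed.
#' @export
asymmetry <- function(curve) {
  stopifnot(inherits(curve, "spoiling_curve"))
  a60 <- curve$alpha_deg[curve$phi0_deg == 60 & !curve$failed]
  a120 <- curve$alpha_deg[curve$phi0_deg == 120 & !curve$failed]
  if (length(a60) != 1 || length(a120) != 1) return(NA_real_)
  a120 - a60
}

#' Grid minimum of a spoiling curve
#'
#' The grid point with the smallest successful flip-angle estimate. No
#' interpolation is performed; ties break toward the smaller increment.
#'
#' @param curve A [spoiling_curve()].
#' @return List with `phi0_deg` and `alpha_deg` of the minimum.
#' @export
curve_minimum <- function(curve) {
  stopifnot(inherits(curve, "spoiling_curve"))
  ok <- !curve$failed & !is.na(curve$alpha_deg)
  if (!any(ok)) stop("all points of the spoiling curve failed")
  i <- which(ok)[which.min(curve$alpha_deg[ok])]  # which.min: first = smaller phi0
  list(phi0_deg = curve$phi0_deg[i], alpha_deg = curve$alpha_deg[i])
}

#' Percent deviation from a reference flip angle
#'
#' @param alpha_deg Measured/simulated flip angle in degrees.
#' @param reference_deg Reference flip angle in degrees (> 0).
#' @return `100 * (alpha - reference) / reference`.
#' @examples
#' percent_deviation(12.6, 60)  # -79
#' @export
percent_deviation <- function(alpha_deg, reference_deg) {
  if (any(reference_deg <= 0)) stop("reference must be positive")
  100 * (alpha_deg - reference_deg) / reference_deg
}

#' Construct a TE series
#'
#' Flip-angle estimates and signal magnitudes over an echo-time grid at fixed
#' spoiling increment.
#'
#' @param te_ms Strictly increasing TE grid in ms.
#' @param alpha_deg Flip-angle estimates (degrees, `NA` = failed).
#' @param s1_mag,s2_mag Signal magnitudes (arbitrary units).
#' @param failed Logical failure markers.
#' @param provenance As in [spoiling_curve()].
#' @return An object of class `te_series` (a data frame).
#' @export
te_series <- function(te_ms, alpha_deg, s1_mag, s2_mag,
                      failed = is.na(alpha_deg), provenance = "simulated") {
  if (any(diff(te_ms) <= 0)) {
    stop("te_ms grid must be strictly increasing")
  }
  out <- data.frame(te_ms = te_ms, alpha_deg = alpha_deg,
                    s1_mag = s1_mag, s2_mag = s2_mag,
                    failed = rep_len(failed, length(te_ms)))
  attr(out, "provenance") <- provenance
  class(out) <- c("te_series", "data.frame")
  out
}

#' @export
print.te_series <- function(x, ...) {
  cat(sprintf("<te_series> %d points (%s), %d failed\n",
              nrow(x), attr(x, "provenance"), sum(x$failed)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Simulate a TE sweep
#'
#' Sweeps the echo time at fixed spoiling increment (default 120 degrees) and
#' records the flip-angle estimate and both signal magnitudes.
#'
#' @inheritParams simulate_spoiling_curve
#' @param te Grid of echo times in ms.
#' @return A [te_series()].
#' @export
simulate_te_sweep <- function(protocol, component,
                              te = seq(1.5, 6.1, by = 0.2), params = NULL,
                              settings = afi_settings()) {
  stopifnot(all(diff(te) > 0))
  one <- function(te_ms) {
    prot <- protocol; prot$te_ms <- te_ms
    if (inherits(component, "two_component_system")) {
      if (is.null(params)) stop("params required for a two-component system")
      sig <- simulate_afi_two_component(prot, component, params, settings)
    } else {
      sig <- simulate_afi(prot, component, settings)
    }
    c(afi_flip_angle(sig, prot$n), Mod(sig$s1), Mod(sig$s2))
  }
  m <- vapply(te, one, numeric(3))
  te_series(te, m[1, ], m[2, ], m[3, ])
}
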