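# Shared physical constants. gamma is the 1H gyromagnetic ratio used for every
# gradient-moment <-> dephasing and ppm <-> Hz conversion in the package.
.const <- list(
  gamma_hz_per_t = 42.577478e6
)

#' Proton gyromagnetic ratio
#'
#' Returns gamma/2pi for 1H in Hz/T, the single value used by all
#' moment-to-dephasing and ppm-to-Hz conversions in this package.
#'
#' @return Numeric scalar, 42.577478e6 Hz/T.
#' @export
gyromagnetic_ratio <- function() .const$gamma_hz_per_t

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' @noRd
wrap_pi <- function(x) {
  # wrap to (-pi, pi]
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}
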