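# Synthetic "measured" inputs: the phantom tube catalog and seeded generators
# of noisy ROI-mean spoiling curves and TE series with the statistical
# structure the analysis assumes (complex Gaussian voxel noise -> Rician
# magnitudes -> ROI statistics over voxel-wise flip-angle estimates).

#' Phantom tube catalog
#'
#' The twelve phantom tubes (PVP1-PVP8 polyvinylpyrrolidone/water mixtures
#' and W1-W4 contrast-agent-doped water) with their dielectric properties and
#' the relaxation/diffusion parameters used for simulation.
#'
#' @return A data frame with one row per tube: `tube`, `pvp_wt_percent`,
#'   `contrast_agent_vol_percent`, `eps_r`, `sigma_S_per_m`, `t1_3t_ms`,
#'   `t1_7t_ms`, `t2_3t_ms`, `t2_7t_ms`, `adc_um2_per_s`.
#' @examples
#' cat <- tube_catalog()
#' subset(cat, tube == "PVP5")
#' @export
tube_catalog <- function() {
  path <- system.file("extdata", "tube_catalog.csv", package = "afisim",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Tissue component for a catalog tube
#'
#' @param tube Tube name (e.g. `"PVP5"`, `"W1"`).
#' @param field `"3T"` or `"7T"`.
#' @return A [tissue_component()] with the tube's T1/T2/ADC at that field.
#' @export
tube_component <- function(tube, field = c("3T", "7T")) {
  field <- match.arg(field)
  cat <- tube_catalog()
  row <- cat[cat$tube == tube, ]
  if (nrow(row) != 1) stop("unknown tube: ", tube)
  if (field == "3T") {
    tissue_component(row$t1_3t_ms, row$t2_3t_ms, row$adc_um2_per_s)
  } else {
    tissue_component(row$t1_7t_ms, row$t2_7t_ms, row$adc_um2_per_s)
  }
}

#' ROI noise model
#'
#' Complex Gaussian noise added per voxel to each AFI signal before the
#' magnitude is taken (Rician magnitudes), followed by ROI statistics over
#' `n_voxels` voxels. All randomness flows from the explicit `seed`.
#'
#' @param complex_noise_sd Standard deviation of each real/imaginary channel
#'   as a fraction of the equilibrium magnetization.
#' @param n_voxels Number of voxels in the ROI.
#' @param seed Integer seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(complex_noise_sd = 0.002, n_voxels = 100L,
                        seed = 1L) {
  stopifnot(complex_noise_sd >= 0, n_voxels >= 1)
  structure(list(complex_noise_sd = complex_noise_sd,
                 n_voxels = as.integer(n_voxels), seed = as.integer(seed)),
            class = "noise_model")
}

# Run fn with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

# ROI statistics of one grid point: add complex noise to (s1, s2), form
# voxel magnitudes, estimate per voxel (or from ROI-mean magnitudes).
roi_point <- function(s1, s2, n, noise, method) {
  nv <- noise$n_voxels
  sd <- noise$complex_noise_sd
  noisy <- function(s) {
    s + complex(real = stats::rnorm(nv, sd = sd),
                imaginary = stats::rnorm(nv, sd = sd))
  }
  m1 <- Mod(noisy(s1)); m2 <- Mod(noisy(s2))
  if (method == "roi_mean") {
    a <- afi_flip_angle(mean(m1), n, mean(m2))
    return(list(alpha = a, sd = 0, failed = is.na(a),
                s1_mag = mean(m1), s2_mag = mean(m2)))
  }
  av <- afi_flip_angle(m1, n, m2)
  ok <- !is.na(av)
  list(alpha = if (any(ok)) mean(av[ok]) else NA_real_,
       sd = if (sum(ok) > 1) stats::sd(av[ok]) else 0,
       failed = !any(ok),
       s1_mag = mean(m1), s2_mag = mean(m2))
}

#' Generate a synthetic noisy measured spoiling curve
#'
#' Simulates the two-frequency model at each spoiling increment, adds
#' independent complex Gaussian voxel noise to both signals, forms Rician
#' magnitudes, estimates the flip angle per voxel and returns the ROI mean
#' and standard deviation per grid point. Reproducible from the noise seed;
#' zero noise returns the noiseless model curve exactly.
#'
#' @param protocol An [afi_protocol()] template.
#' @param system A [two_component_system()].
#' @param params An [interference_params()].
#' @param truth_alpha True flip angle played out, in degrees.
#' @param noise A [noise_model()].
#' @param phi0 Grid of spoiling increments (degrees).
#' @param settings An [afi_settings()] list.
#' @param components Optional precomputed [simulate_components()] table
#'   (must match `phi0` and `truth_alpha`).
#' @param method `"voxelwise"` (ROI statistics over voxel-wise flip-angle
#'   estimates, mirroring how ROIs on flip-angle maps behave) or
#'   `"roi_mean"` (single estimate from ROI-mean magnitudes).
#' @return A [spoiling_curve()] with provenance `"synthetic-measured"`.
#' @export
generate_measured_curve <- function(protocol, system, params, truth_alpha,
                                    noise = noise_model(),
                                    phi0 = seq(0, 180, by = 20),
                                    settings = afi_settings(),
                                    components = NULL,
                                    method = c("voxelwise", "roi_mean")) {
  method <- match.arg(method)
  prot <- protocol
  prot$alpha_deg <- truth_alpha
  if (is.null(components)) {
    components <- simulate_components(prot, system, phi0, settings)
  }
  cmb <- combine_components(components, params)
  if (noise$complex_noise_sd == 0) {
    return(spoiling_curve(phi0, cmb$alpha_deg,
                          reference_alpha = truth_alpha,
                          provenance = "synthetic-measured"))
  }
  pts <- with_seed(noise$seed, function() {
    lapply(seq_along(phi0), function(i) {
      roi_point(cmb$s1[i], cmb$s2[i], prot$n, noise, method)
    })
  })
  spoiling_curve(phi0,
                 vapply(pts, `[[`, numeric(1), "alpha"),
                 vapply(pts, `[[`, numeric(1), "sd"),
                 vapply(pts, `[[`, logical(1), "failed"),
                 reference_alpha = truth_alpha,
                 provenance = "synthetic-measured")
}

#' Generate a synthetic noisy TE series
#'
#' As [generate_measured_curve()] but sweeping the echo time at fixed
#' spoiling increment, also emitting the ROI-mean signal magnitudes.
#'
#' @inheritParams generate_measured_curve
#' @param te Grid of echo times in ms.
#' @return A [te_series()] with provenance `"synthetic-measured"`.
#' @export
generate_te_series <- function(protocol, system, params, truth_alpha,
                               noise = noise_model(),
                               te = seq(1.5, 6.1, by = 0.2),
                               settings = afi_settings(),
                               method = c("voxelwise", "roi_mean")) {
  method <- match.arg(method)
  prot <- protocol
  prot$alpha_deg <- truth_alpha
  sims <- lapply(te, function(te_ms) {
    pr <- prot; pr$te_ms <- te_ms
    simulate_afi_two_component(pr, system, params, settings)
  })
  s1 <- vapply(sims, function(s) s$s1, complex(1))
  s2 <- vapply(sims, function(s) s$s2, complex(1))
  if (noise$complex_noise_sd == 0) {
    return(te_series(te, afi_flip_angle(s1, prot$n, s2), Mod(s1), Mod(s2),
                     provenance = "synthetic-measured"))
  }
  pts <- with_seed(noise$seed, function() {
    lapply(seq_along(te), function(i) {
      roi_point(s1[i], s2[i], prot$n, noise, method)
    })
  })
  te_series(te,
            vapply(pts, `[[`, numeric(1), "alpha"),
            vapply(pts, `[[`, numeric(1), "s1_mag"),
            vapply(pts, `[[`, numeric(1), "s2_mag"),
            vapply(pts, `[[`, logical(1), "failed"),
            provenance = "synthetic-measured")
}
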