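# Fit the interference parameters (w, phi) of the two-frequency model by
# minimizing the RMS deviation between simulated and measured spoiling
# curves. The per-pool component signals do not depend on (w, phi), so they
# are simulated once per grid and every candidate is evaluated by scalar
# combination; a deterministic coarse grid search seeds Nelder-Mead
# refinements from the best starts.

#' RMS deviation between two spoiling curves
#'
#' Root of the mean squared flip-angle difference over grid points successful
#' in both curves.
#'
#' @param curve_a,curve_b [spoiling_curve()] objects on identical phi0 grids.
#' @return RMSE in degrees, with attribute `n_points` (points compared).
#' @examples
#' a <- spoiling_curve(c(0, 20), c(50, 53))
#' b <- spoiling_curve(c(0, 20), c(53, 57))
#' rmse_curves(a, b)  # sqrt((9 + 16)/2)
#' @export
rmse_curves <- function(curve_a, curve_b) {
  stopifnot(inherits(curve_a, "spoiling_curve"),
            inherits(curve_b, "spoiling_curve"))
  if (!isTRUE(all.equal(curve_a$phi0_deg, curve_b$phi0_deg))) {
    stop("phi0 grids differ between the two curves")
  }
  ok <- !curve_a$failed & !curve_b$failed &
    !is.na(curve_a$alpha_deg) & !is.na(curve_b$alpha_deg)
  if (!any(ok)) stop("no mutually successful grid points")
  d <- curve_a$alpha_deg[ok] - curve_b$alpha_deg[ok]
  structure(sqrt(mean(d^2)), n_points = sum(ok))
}

# Objective for a candidate (w, phi): RMSE over measured-successful points,
# with simulated failures at those points penalized at 90 degrees each.
fit_objective <- function(w, phi, components, measured, te_ms, delta_nu_hz,
                          penalty_deg = 90) {
  if (w < 0 || w > 1) return(1e6 + abs(w) * 1e3)
  pars <- interference_params(w = w, phi = phi, delta_nu_hz = delta_nu_hz)
  sim <- combine_components(components, pars, te_ms)
  ok_meas <- !measured$failed & !is.na(measured$alpha_deg)
  d <- sim$alpha_deg[ok_meas] - measured$alpha_deg[ok_meas]
  d[is.na(d)] <- penalty_deg
  sqrt(mean(d^2))
}

#' Fit the two-frequency interference parameters to a measured spoiling curve
#'
#' Estimates the off-resonant weight `w` and phase offset `phi` of the
#' two-frequency interference model by minimizing the root-mean-square
#' deviation between the model spoiling curve and a measured one, with the
#' resonance offset held fixed. The search is a deterministic coarse grid
#' (default 21 weights x 24 phases, phase treated on the circle) followed by
#' Nelder-Mead refinement from the best `n_starts` grid points. Grid points
#' where the measured estimate failed are excluded from the objective;
#' candidate parameters whose simulated estimate fails at a measured-valid
#' point are penalized, not fatal.
#'
#' @param measured A [spoiling_curve()] with at least 4 successful points.
#' @param protocol The [afi_protocol()] of the measurement (TE, moments,
#'   flip angle); `phi0_deg` is taken from the measured grid.
#' @param system A [two_component_system()] with the pool parameters.
#' @param delta_nu_hz Resonance offset held fixed during the fit; defaults to
#'   the system's off-pool offset.
#' @param settings [afi_settings()] for the component simulations.
#' @param w_grid,phi_grid Coarse-search resolution (number of grid values).
#' @param n_starts Number of grid starts refined by Nelder-Mead.
#' @param components Optional precomputed [simulate_components()] table on the
#'   measured grid (reused across fits of replicate curves).
#' @return An object of class `afi_interference_fit` with components
#'   `params` ([interference_params()]), `rmse` (degrees, over mutually
#'   successful points), `n_points`, `diagnostics` (grid starts, convergence
#'   flags, runner-up optima, excluded points), `measured`, `fitted_curve`,
#'   and the protocol/system/components used. Supports `print()`,
#'   `summary()`, `coef()`, `predict()`, `fitted()`, `residuals()`, `plot()`
#'   and `simulate()`.
#' @examples
#' \donttest{
#' sys <- two_component_system(tissue_component(1292, 780, 990),
#'                             pvp_off_pool(23, 990, 320))
#' prot <- afi_protocol()
#' truth <- interference_params(w = 0.136, phi_pi = -0.18, delta_nu_hz = 320)
#' meas <- simulate_spoiling_curve(prot, sys, params = truth)
#' fit <- fit_interference(meas, prot, sys)
#' coef(fit)
#' }
#' @export
fit_interference <- function(measured, protocol, system,
                             delta_nu_hz = system$off$delta_nu_hz,
                             settings = afi_settings(),
                             w_grid = 21, phi_grid = 24, n_starts = 3,
                             components = NULL) {
  stopifnot(inherits(measured, "spoiling_curve"))
  ok_meas <- !measured$failed & !is.na(measured$alpha_deg)
  if (sum(ok_meas) < 4) {
    stop("measured curve needs at least 4 successful points")
  }
  if (is.null(components)) {
    components <- simulate_components(protocol, system, measured$phi0_deg,
                                      settings)
  } else {
    if (!isTRUE(all.equal(components$phi0_deg, measured$phi0_deg))) {
      stop("components grid does not match the measured grid")
    }
  }
  te_ms <- protocol$te_ms
  obj <- function(par) fit_objective(par[1], par[2], components, measured,
                                     te_ms, delta_nu_hz)
  ws <- seq(0, 1, length.out = w_grid)
  phis <- seq(-pi, pi, length.out = phi_grid + 1)[-1]  # evenly on the circle
  grid <- expand.grid(w = ws, phi = phis)
  grid$rmse <- vapply(seq_len(nrow(grid)),
                      function(i) obj(c(grid$w[i], grid$phi[i])), numeric(1))
  ord <- order(grid$rmse)
  starts <- grid[ord[seq_len(min(n_starts, nrow(grid)))], ]
  refine <- lapply(seq_len(nrow(starts)), function(i) {
    stats::optim(c(starts$w[i], starts$phi[i]), obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 2000))
  })
  vals <- vapply(refine, function(r) r$value, numeric(1))
  best <- refine[[which.min(vals)]]
  pars <- interference_params(w = max(best$par[1], 0),
                              phi = wrap_pi(best$par[2]),
                              delta_nu_hz = delta_nu_hz)
  sim <- combine_components(components, pars, te_ms)
  fitted_curve <- spoiling_curve(measured$phi0_deg, sim$alpha_deg,
                                 reference_alpha = protocol$alpha_deg,
                                 provenance = "simulated")
  final_rmse <- rmse_curves(fitted_curve, measured)
  structure(
    list(params = pars,
         rmse = as.numeric(final_rmse),
         n_points = attr(final_rmse, "n_points"),
         diagnostics = list(
           starts = starts,
           convergence = vapply(refine, function(r) r$convergence,
                                numeric(1)),
           runner_up = lapply(refine, function(r) {
             list(w = r$par[1], phi = wrap_pi(r$par[2]), rmse = r$value)
           }),
           excluded = measured$phi0_deg[!ok_meas]),
         measured = measured,
         fitted_curve = fitted_curve,
         components = components,
         protocol = protocol,
         system = system,
         settings = settings,
         call = match.call()),
    class = "afi_interference_fit"
  )
}

#' @export
print.afi_interference_fit <- function(x, ...) {
  cat("Two-frequency interference fit\n")
  cat(sprintf("  w = %.4f, phi = %.4f*pi (dnu = %g Hz, fixed)\n",
              x$params$w, x$params$phi / pi, x$params$delta_nu_hz))
  cat(sprintf("  RMSE = %.4g deg over %d points", x$rmse, x$n_points))
  if (length(x$diagnostics$excluded)) {
    cat(sprintf(" (%d failed points excluded)",
                length(x$diagnostics$excluded)))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.afi_interference_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.afi_interference_fit")
}

#' @export
print.summary.afi_interference_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nProtocol:\n"); print(f$protocol)
  cat("Runner-up optima (per refinement start):\n")
  for (r in f$diagnostics$runner_up) {
    cat(sprintf("  w = %.4f, phi = %.4f*pi, rmse = %.4g\n",
                r$w, r$phi / pi, r$rmse))
  }
  cat("Residuals (deg):\n")
  print(stats::setNames(round(stats::residuals(f), 4),
                        f$measured$phi0_deg))
  invisible(x)
}

#' @export
coef.afi_interference_fit <- function(object, ...) {
  c(w = object$params$w, phi = object$params$phi,
    delta_nu_hz = object$params$delta_nu_hz)
}

#' Predict the model spoiling curve of a fit
#'
#' @param object An `afi_interference_fit`.
#' @param phi0 Optional new grid of spoiling increments (degrees); component
#'   signals are re-simulated when it differs from the fitted grid.
#' @param te_ms Optional echo time for the combination (defaults to the
#'   fitted protocol's).
#' @param ... Unused.
#' @return A [spoiling_curve()] of model flip angles at the fitted
#'   parameters.
#' @export
predict.afi_interference_fit <- function(object, phi0 = NULL, te_ms = NULL,
                                         ...) {
  comp <- object$components
  if (!is.null(phi0) && !isTRUE(all.equal(phi0, comp$phi0_deg))) {
    comp <- simulate_components(object$protocol, object$system, phi0,
                                object$settings)
  }
  sim <- combine_components(comp, object$params, te_ms)
  spoiling_curve(comp$phi0_deg, sim$alpha_deg,
                 reference_alpha = object$protocol$alpha_deg,
                 provenance = "simulated")
}

#' @export
fitted.afi_interference_fit <- function(object, ...) {
  object$fitted_curve$alpha_deg
}

#' @export
residuals.afi_interference_fit <- function(object, ...) {
  object$measured$alpha_deg - object$fitted_curve$alpha_deg
}

#' @export
plot.afi_interference_fit <- function(x, ...) {
  ylim <- range(c(x$measured$alpha_deg, x$fitted_curve$alpha_deg,
                  x$protocol$alpha_deg), na.rm = TRUE)
  plot(x$measured, ylim = ylim, col = 1,
       main = sprintf("w = %.3f, phi = %.2f*pi, RMSE = %.2f deg",
                      x$params$w, x$params$phi / pi, x$rmse), ...)
  lines(x$fitted_curve$phi0_deg, x$fitted_curve$alpha_deg, col = 2)
  legend("bottomright", c("measured", "fitted model"), col = 1:2,
         pch = c(16, NA), lty = c(NA, 1), bty = "n")
  invisible(x)
}

#' Simulate noisy replicate curves from a fit
#'
#' Draws synthetic noisy ROI-mean spoiling curves at the fitted parameters
#' (see [generate_measured_curve()]).
#'
#' @param object An `afi_interference_fit`.
#' @param nsim Number of replicate curves.
#' @param seed Integer seed for the noise draws.
#' @param noise A [noise_model()]; its seed is offset per replicate.
#' @param ... Unused.
#' @return A list of `nsim` [spoiling_curve()] objects.
#' @export
simulate.afi_interference_fit <- function(object, nsim = 1, seed = 1,
                                          noise = noise_model(seed = seed),
                                          ...) {
  lapply(seq_len(nsim), function(i) {
    nm <- noise
    nm$seed <- noise$seed + i - 1L
    generate_measured_curve(object$protocol, object$system, object$params,
                            truth_alpha = object$protocol$alpha_deg,
                            noise = nm, phi0 = object$measured$phi0_deg,
                            settings = object$settings,
                            components = object$components)
  })
}
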