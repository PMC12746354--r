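# Configuration, file formats and run entry points. Curves and TE series are
# exchanged as plain CSV (comma separator, '.' decimal, header row, angles
# with 4 decimals) with a JSON sidecar carrying the protocol, provenance,
# package version and a config hash so any output can be re-derived from its
# sidecar.

# FNV-1a hash of a character scalar; stable fingerprint for sidecars.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

protocol_to_list <- function(p) {
  list(tr1_ms = p$tr1_ms, tr2_ms = p$tr2_ms, te_ms = p$te_ms,
       alpha_nom_deg = p$alpha_deg, phi0_deg = p$phi0_deg,
       a_g1_mTms_per_m = p$a_g1, a_g2_mTms_per_m = p$a_g2,
       pulse_ms = p$pulse_ms, voxel_mm = p$voxel_mm)
}

protocol_from_list <- function(l) {
  afi_protocol(tr1_ms = l$tr1_ms, tr2_ms = l$tr2_ms, te_ms = l$te_ms,
               alpha_deg = l$alpha_nom_deg, phi0_deg = l$phi0_deg %||% 120,
               a_g1 = l$a_g1_mTms_per_m, a_g2 = l$a_g2_mTms_per_m,
               pulse_ms = l$pulse_ms %||% 0.5, voxel_mm = l$voxel_mm %||% 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration
#'
#' Parses a YAML (or JSON) run configuration with blocks `protocol`
#' (keys `tr1_ms`, `tr2_ms`, `te_ms`, `alpha_nom_deg`, `phi0_deg`,
#' `a_g1_mTms_per_m`, `a_g2_mTms_per_m`, `pulse_ms`, `voxel_mm`), `tissue`
#' (either `tube` + `field`, or explicit `t1_ms`/`t2_ms`/`adc_um2_s`),
#' optional `off_pool` (`t1_ms`, `t2_ms`, `delta_nu_hz`), optional
#' `interference` (`w`, `phi_pi`, `delta_nu_hz`), optional `sweep`
#' (`phi0_grid` or `te_grid`), optional `noise` (`complex_noise_sd`,
#' `n_voxels`, `seed`) and optional `settings` overrides.
#'
#' @param path Path to the YAML/JSON config file.
#' @return A validated list of class `run_config` with parsed `protocol`,
#'   `component` (tissue or two-component system), `params`, grids, `noise`,
#'   `settings` and the raw text's hash.
#' @export
read_run_config <- function(path) {
  raw <- readLines(path, warn = FALSE)
  cfg <- yaml::yaml.load(paste(raw, collapse = "\n"))
  if (is.null(cfg$protocol)) stop("config field missing: protocol")
  protocol <- protocol_from_list(cfg$protocol)
  tissue <- cfg$tissue
  if (is.null(tissue)) stop("config field missing: tissue")
  res <- if (!is.null(tissue$tube)) {
    tube_component(tissue$tube, tissue$field %||% "3T")
  } else {
    tissue_component(tissue$t1_ms, tissue$t2_ms, tissue$adc_um2_s %||% 0)
  }
  component <- res
  params <- NULL
  if (!is.null(cfg$off_pool)) {
    off <- tissue_component(cfg$off_pool$t1_ms, cfg$off_pool$t2_ms,
                            res$adc_um2_s,
                            delta_nu_hz = cfg$off_pool$delta_nu_hz)
    component <- two_component_system(res, off)
    if (is.null(cfg$interference)) {
      stop("config field missing: interference (required with off_pool)")
    }
    params <- interference_params(w = cfg$interference$w,
                                  phi_pi = cfg$interference$phi_pi,
                                  delta_nu_hz = cfg$interference$delta_nu_hz
                                  %||% off$delta_nu_hz)
  }
  st <- afi_settings()
  for (k in names(cfg$settings %||% list())) {
    if (!k %in% names(st)) stop("unknown settings field: ", k)
    st[[k]] <- cfg$settings[[k]]
  }
  noise <- if (!is.null(cfg$noise)) {
    noise_model(cfg$noise$complex_noise_sd %||% 0.002,
                cfg$noise$n_voxels %||% 100L,
                cfg$noise$seed %||% 1L)
  }
  structure(
    list(protocol = protocol, component = component, params = params,
         phi0_grid = cfg$sweep$phi0_grid %||% seq(0, 180, by = 20),
         te_grid = cfg$sweep$te_grid %||% seq(1.5, 6.1, by = 0.2),
         noise = noise, settings = st, hash = config_hash(raw)),
    class = "run_config"
  )
}

sidecar <- function(cfg, extra = list()) {
  c(list(package = "afisim",
         version = as.character(utils::packageVersion("afisim")),
         config_hash = cfg$hash,
         protocol = protocol_to_list(cfg$protocol)),
    extra)
}

write_sidecar <- function(path, cfg, extra = list()) {
  jsonlite::write_json(sidecar(cfg, extra), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
}

fmt4 <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x))

#' Write / read a spoiling curve as CSV
#'
#' Columns `phi0_deg`, `alpha_deg`, `alpha_sd_deg`, `failed`; angles with 4
#' decimals.
#'
#' @param curve A [spoiling_curve()].
#' @param path Output / input CSV path.
#' @return `write_spoiling_curve()` returns `path` invisibly;
#'   `read_spoiling_curve()` returns a [spoiling_curve()] with provenance
#'   `"file"`.
#' @export
write_spoiling_curve <- function(curve, path) {
  stopifnot(inherits(curve, "spoiling_curve"))
  d <- data.frame(phi0_deg = fmt4(curve$phi0_deg),
                  alpha_deg = fmt4(curve$alpha_deg),
                  alpha_sd_deg = fmt4(curve$alpha_sd_deg),
                  failed = tolower(as.character(curve$failed)))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spoiling_curve
#' @export
read_spoiling_curve <- function(path) {
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) stop("malformed CSV ", path, ": ",
                                         conditionMessage(e)))
  need <- c("phi0_deg", "alpha_deg", "alpha_sd_deg", "failed")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("CSV ", path, " lacks columns: ", paste(miss, collapse = ", "),
         " (header is line 1)")
  }
  spoiling_curve(as.numeric(d$phi0_deg), as.numeric(d$alpha_deg),
                 as.numeric(d$alpha_sd_deg),
                 as.logical(toupper(d$failed)), provenance = "file")
}

#' Write / read a TE series as CSV
#'
#' Columns `te_ms`, `alpha_deg`, `s1_mag`, `s2_mag`, `failed`.
#'
#' @param series A [te_series()].
#' @param path Output / input CSV path.
#' @return `write_te_series()` returns `path` invisibly; `read_te_series()`
#'   returns a [te_series()].
#' @export
write_te_series <- function(series, path) {
  stopifnot(inherits(series, "te_series"))
  d <- data.frame(te_ms = fmt4(series$te_ms),
                  alpha_deg = fmt4(series$alpha_deg),
                  s1_mag = sprintf("%.6g", series$s1_mag),
                  s2_mag = sprintf("%.6g", series$s2_mag),
                  failed = tolower(as.character(series$failed)))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_te_series
#' @export
read_te_series <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  te_series(as.numeric(d$te_ms), as.numeric(d$alpha_deg),
            as.numeric(d$s1_mag), as.numeric(d$s2_mag),
            as.logical(toupper(d$failed)), provenance = "file")
}

#' Run a configured spoiling-curve simulation to files
#'
#' Simulates the spoiling curve described by a [read_run_config()] object and
#' writes `spoiling_curve.csv` plus a JSON sidecar into `out_dir`.
#'
#' @param cfg A `run_config`.
#' @param out_dir Output directory (created if missing).
#' @return Invisible character vector of the files written.
#' @export
afi_run_spoiling_curve <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  crv <- simulate_spoiling_curve(cfg$protocol, cfg$component,
                                 phi0 = cfg$phi0_grid, params = cfg$params,
                                 settings = cfg$settings)
  csv <- file.path(out_dir, "spoiling_curve.csv")
  js <- file.path(out_dir, "spoiling_curve.json")
  write_spoiling_curve(crv, csv)
  write_sidecar(js, cfg, list(provenance = attr(crv, "provenance"),
                              phi0_grid = cfg$phi0_grid))
  invisible(c(csv, js))
}

#' Run a configured TE sweep to files
#'
#' @inheritParams afi_run_spoiling_curve
#' @return Invisible character vector of the files written.
#' @export
afi_run_te_sweep <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ts <- simulate_te_sweep(cfg$protocol, cfg$component, te = cfg$te_grid,
                          params = cfg$params, settings = cfg$settings)
  csv <- file.path(out_dir, "te_series.csv")
  js <- file.path(out_dir, "te_series.json")
  write_te_series(ts, csv)
  write_sidecar(js, cfg, list(provenance = attr(ts, "provenance"),
                              te_grid = cfg$te_grid))
  invisible(c(csv, js))
}

#' Generate a synthetic noisy measured curve to files
#'
#' @inheritParams afi_run_spoiling_curve
#' @param seed Optional seed overriding the config's noise seed.
#' @return Invisible character vector of the files written.
#' @export
afi_run_synth <- function(cfg, out_dir, seed = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (!inherits(cfg$component, "two_component_system")) {
    stop("synth requires a two-component system (off pool) in the config")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  noise <- cfg$noise %||% noise_model()
  if (!is.null(seed)) noise$seed <- as.integer(seed)
  crv <- generate_measured_curve(cfg$protocol, cfg$component, cfg$params,
                                 truth_alpha = cfg$protocol$alpha_deg,
                                 noise = noise, phi0 = cfg$phi0_grid,
                                 settings = cfg$settings)
  csv <- file.path(out_dir, "synthetic_curve.csv")
  js <- file.path(out_dir, "synthetic_curve.json")
  write_spoiling_curve(crv, csv)
  write_sidecar(js, cfg, list(provenance = attr(crv, "provenance"),
                              seed = noise$seed,
                              complex_noise_sd = noise$complex_noise_sd,
                              n_voxels = noise$n_voxels))
  invisible(c(csv, js))
}

#' Fit interference parameters from a measured-curve CSV to files
#'
#' @inheritParams afi_run_spoiling_curve
#' @param measured_csv Path to a spoiling-curve CSV (see
#'   [read_spoiling_curve()]).
#' @return Invisible path of the JSON result written.
#' @export
afi_run_fit <- function(cfg, measured_csv, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  if (!inherits(cfg$component, "two_component_system")) {
    stop("fit requires a two-component system (off pool) in the config")
  }
  measured <- read_spoiling_curve(measured_csv)
  if (!isTRUE(all.equal(measured$phi0_deg, as.numeric(cfg$phi0_grid)))) {
    stop("grid mismatch between measured curve and config phi0_grid")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- fit_interference(measured, cfg$protocol, cfg$component,
                          settings = cfg$settings)
  out <- file.path(out_dir, "fit_result.json")
  jsonlite::write_json(
    list(w = fit$params$w,
         phi_pi_units = fit$params$phi / pi,
         phi_units = "pi",
         delta_nu_hz = fit$params$delta_nu_hz,
         rmse_deg = fit$rmse,
         n_points = fit$n_points,
         settings_hash = config_hash(paste(
           names(unlist(cfg$settings)), unlist(cfg$settings),
           collapse = ";")),
         config_hash = cfg$hash),
    out, auto_unbox = TRUE, digits = NA)
  message(sprintf("fit: w = %.4f, phi = %.4f*pi, rmse = %.4g deg",
                  fit$params$w, fit$params$phi / pi, fit$rmse))
  invisible(out)
}
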