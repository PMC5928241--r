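#' Simulation configuration for the synthetic methylation experiment
#'
#' Bundles every parameter of the synthetic array experiment: the exposure
#' design (doses in Gy, sampling times in days, replicates), the bimodal
#' baseline beta distribution, planted dose effects and slow methylation
#' drift, chip/row batch structure, measurement noise, and detection
#' failures. The defaults describe a heavy-ion exposure series: 4 doses
#' (0-1 Gy) times 4 time points (2-55 days) in biological triplicate,
#' assayed on 12-sample chips.
#'
#' @param n_probes number of CpG probes on the synthetic array.
#' @param doses numeric vector of radiation doses in Gy (must include the
#'   design's levels; 0 Gy recommended as the control).
#' @param time_points numeric vector of days after exposure at which samples
#'   are collected.
#' @param n_replicates biological replicates per dose-by-time cell.
#' @param baseline_mixture list with `weights`, `means`, `concentrations` of
#'   a two-component beta mixture describing baseline methylation: a
#'   low-beta mode (unmethylated CpG-island-like probes) and a high-beta
#'   mode (methylated gene-body/intergenic probes).
#' @param n_dose_probes number of probes with a planted linear dose effect.
#' @param dose_effect magnitude of the planted slope, in beta units per Gy.
#'   The sign per probe follows `effect_profile`.
#' @param effect_profile one of `"fe_like"` (hypermethylation at
#'   low-baseline sites, the iron-ion pattern), `"si_like"` (mixed
#'   directions at intermediate-baseline sites, the silicon-ion pattern) or
#'   `"x_like"` (hypomethylation at high-baseline sites, the X-ray pattern).
#' @param n_drift_probes number of probes drifting with time in culture.
#' @param drift_rate drift magnitude in beta units per day (default 0.001,
#'   i.e. one molecule per thousand shifting methylation state per day);
#'   per-probe direction is a fixed random sign.
#' @param n_both_probes number of probes carrying both a dose effect and
#'   drift (default 0).
#' @param chip_sd standard deviation of the per-chip random intercept
#'   (beta units).
#' @param row_sd standard deviation of the per-row effect (beta units).
#' @param residual_sd per-observation noise on the latent beta scale.
#' @param total_intensity expected methylated + unmethylated signal (AU).
#' @param detection_fail_rate probability that a data point receives a
#'   failing detection p-value (> 0.001).
#' @param series label for the exposure series.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output from every generator.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_probes = 500, seed = 1)
#' sheet <- generate_sample_sheet(cfg)
#' nrow(sheet) # 4 doses x 4 times x 3 replicates = 48
sim_config <- function(n_probes = 20000,
                       doses = c(0, 0.1, 0.3, 1.0),
                       time_points = c(2, 20, 37, 55),
                       n_replicates = 3,
                       baseline_mixture = list(weights = c(0.6, 0.4),
                                               means = c(0.15, 0.85),
                                               concentrations = c(15, 15)),
                       n_dose_probes = 200,
                       dose_effect = 0.05,
                       effect_profile = c("fe_like", "si_like", "x_like"),
                       n_drift_probes = 500,
                       drift_rate = 0.001,
                       n_both_probes = 0,
                       chip_sd = 0.02,
                       row_sd = 0.01,
                       residual_sd = 0.02,
                       total_intensity = 10000,
                       detection_fail_rate = 0.002,
                       series = "sim",
                       seed) {
  if (missing(seed)) stop_bad_arg("seed", "a seed is mandatory")
  if (!is_count(seed)) stop_bad_arg("seed", "must be a non-negative integer")
  effect_profile <- match.arg(effect_profile)
  for (nm in c("n_probes", "n_replicates", "n_dose_probes", "n_drift_probes",
               "n_both_probes")) {
    if (!is_count(get(nm))) stop_bad_arg(nm, "must be a non-negative count")
  }
  if (n_probes < 1) stop_bad_arg("n_probes", "must be positive")
  if (length(doses) < 1 || length(time_points) < 1 || n_replicates < 1)
    stop("design lists (doses, time_points, n_replicates) must be non-empty",
         call. = FALSE)
  if (!all(is.finite(doses)) || any(doses < 0))
    stop_bad_arg("doses", "must be finite and non-negative (Gy)")
  if (!all(is.finite(time_points)) || any(time_points < 0))
    stop_bad_arg("time_points", "must be finite and non-negative (days)")
  check_fraction(detection_fail_rate, "detection_fail_rate")
  for (nm in c("dose_effect", "drift_rate", "chip_sd", "row_sd",
               "residual_sd", "total_intensity")) {
    if (!is_number(get(nm))) stop_bad_arg(nm, "must be a finite number")
  }
  if (chip_sd < 0 || row_sd < 0 || residual_sd < 0)
    stop("standard deviations must be non-negative", call. = FALSE)
  if (total_intensity <= 0)
    stop_bad_arg("total_intensity", "must be positive")
  bm <- baseline_mixture
  if (!is.list(bm) ||
      !all(c("weights", "means", "concentrations") %in% names(bm)) ||
      length(bm$weights) != 2 || length(bm$means) != 2 ||
      length(bm$concentrations) != 2)
    stop_bad_arg("baseline_mixture",
                 "needs two-component weights, means and concentrations")
  if (abs(sum(bm$weights) - 1) > 1e-8 || any(bm$weights < 0))
    stop_bad_arg("baseline_mixture", "weights must be non-negative, sum 1")
  if (any(bm$means <= 0) || any(bm$means >= 1) || any(bm$concentrations <= 0))
    stop_bad_arg("baseline_mixture",
                 "means must lie in (0,1), concentrations must be positive")
  if (n_dose_probes + n_drift_probes + n_both_probes > n_probes)
    stop("n_dose_probes + n_drift_probes + n_both_probes exceeds n_probes",
         call. = FALSE)
  structure(list(
    n_probes = as.integer(n_probes), doses = as.numeric(doses),
    time_points = as.numeric(time_points),
    n_replicates = as.integer(n_replicates),
    baseline_mixture = bm,
    n_dose_probes = as.integer(n_dose_probes),
    dose_effect = dose_effect, effect_profile = effect_profile,
    n_drift_probes = as.integer(n_drift_probes), drift_rate = drift_rate,
    n_both_probes = as.integer(n_both_probes),
    chip_sd = chip_sd, row_sd = row_sd, residual_sd = residual_sd,
    total_intensity = total_intensity,
    detection_fail_rate = detection_fail_rate,
    series = as.character(series), seed = as.integer(seed)
  ), class = "sim_config")
}

#' Read a simulation configuration from a JSON or YAML document
#'
#' The document holds any subset of [sim_config()] arguments; `seed` is
#' mandatory. Files ending in `.json` are parsed with jsonlite, everything
#' else with yaml.
#'
#' @param path path to the config document.
#' @return a `sim_config` object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(sim_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown config fields: ", paste(extra, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, raw)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d probes; %d doses x %d times x %d reps (%d samples)\n",
    x$n_probes, length(x$doses), length(x$time_points), x$n_replicates,
    length(x$doses) * length(x$time_points) * x$n_replicates))
  cat(sprintf("  planted: %d dose (%+.3g b/Gy, %s), %d drift (%.3g b/day), %d both\n",
              x$n_dose_probes, x$dose_effect, x$effect_profile,
              x$n_drift_probes, x$drift_rate, x$n_both_probes))
  cat(sprintf("  noise: chip %.3g, row %.3g, residual %.3g; seed %d\n",
              x$chip_sd, x$row_sd, x$residual_sd, x$seed))
  invisible(x)
}
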