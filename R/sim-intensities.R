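#' Construct an intensity matrix object
#'
#' Container for methylated (M) and unmethylated (U) bead-type signals plus
#' per-datapoint detection p-values, all probes x samples with shared
#' dimnames.
#'
#' @param M,U,detection_p numeric matrices, probes x samples.
#' @return object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(M, U, detection_p) {
  if (!identical(dim(M), dim(U)) || !identical(dim(M), dim(detection_p)))
    stop("M, U and detection_p must share dimensions", call. = FALSE)
  if (!identical(dimnames(M), dimnames(U)) ||
      !identical(dimnames(M), dimnames(detection_p)))
    stop("M, U and detection_p must share dimnames", call. = FALSE)
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
    stop("signals must be non-negative", call. = FALSE)
  if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE))
    stop("detection p-values must lie in [0, 1]", call. = FALSE)
  structure(list(M = M, U = U, detection_p = detection_p),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d probes x %d samples\n",
              nrow(x$M), ncol(x$M)))
  invisible(x)
}

#' Simulate probe intensities with planted dose effects and drift
#'
#' Builds the latent methylation proportion per probe and sample as
#' baseline + dose effect (planted probes only) + drift x days (drift
#' probes) + chip random intercept + row effect + residual noise, clamped
#' to `[0.001, 0.999]`, then emits methylated/unmethylated signals. With
#' `residual_sd > 0` the methylated count is binomial with size
#' `total_intensity`; with `residual_sd = 0` signals are exactly
#' `M = beta * total_intensity` (noise-free identity). Detection p-values
#' are < 0.001 except for a `detection_fail_rate` fraction of datapoints
#' drawn above that cutoff.
#'
#' Baselines come from the configured two-component beta mixture, except at
#' planted dose probes, where the effect profile couples direction to
#' baseline: `fe_like` probes start in the low-beta mode and gain
#' methylation, `x_like` probes start in the high-beta mode and lose it,
#' `si_like` probes start at intermediate levels with mixed directions.
#'
#' @param config a [sim_config()] object.
#' @param sheet sample sheet from [generate_sample_sheet()].
#' @param probes probe manifest from [probe_manifest()] or
#'   [generate_probe_annotation()].
#' @return an [intensity_matrix()]; the latent truth (per-probe baseline,
#'   effect, drift sign and the latent beta matrix) is attached as
#'   `attr(, "truth")`.
#' @export
generate_intensities <- function(config, sheet, probes) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(sheet) == 0 || nrow(probes) == 0)
    stop("sheet and probes must be non-empty", call. = FALSE)
  for (nm in c("chip_sd", "row_sd", "residual_sd", "total_intensity",
               "dose_effect", "drift_rate"))
    if (!is.finite(config[[nm]])) stop_bad_arg(nm, "must be finite")
  n <- nrow(probes); m <- nrow(sheet)
  T_int <- config$total_intensity
  bm <- config$baseline_mixture

  with_seed(config$seed + 3L, {
    comp <- sample.int(2, n, replace = TRUE, prob = bm$weights)
    baseline <- rbeta_mc(n, bm$means[comp], bm$concentrations[comp])
    dose_idx <- which(probes$is_dose)
    if (length(dose_idx)) {
      k <- length(dose_idx)
      baseline[dose_idx] <- switch(config$effect_profile,
        fe_like = rbeta_mc(k, rep(bm$means[1], k),
                           rep(bm$concentrations[1], k)),
        x_like = rbeta_mc(k, rep(bm$means[2], k),
                          rep(bm$concentrations[2], k)),
        si_like = stats::runif(k, 0.4, 0.8))
    }
    chip_levels <- sort(unique(sheet$chip))
    row_levels <- sort(unique(sheet$row))
    chip_eff <- stats::rnorm(length(chip_levels), 0, config$chip_sd)
    row_eff <- stats::rnorm(length(row_levels), 0, config$row_sd)
    sample_shift <- chip_eff[match(sheet$chip, chip_levels)] +
      row_eff[match(sheet$row, row_levels)]

    latent <- matrix(baseline, n, m) +
      outer(probes$effect, sheet$dose) +
      outer(probes$drift_sign * config$drift_rate, sheet$time)
    latent <- sweep(latent, 2, sample_shift, "+")
    if (config$residual_sd > 0)
      latent <- latent + matrix(stats::rnorm(n * m, 0, config$residual_sd),
                                n, m)
    latent <- clamp(latent, 0.001, 0.999)

    if (config$residual_sd > 0) {
      T_size <- round(T_int)
      M <- matrix(stats::rbinom(n * m, size = T_size, prob = latent), n, m)
    } else {
      T_size <- T_int
      M <- latent * T_int
    }
    U <- T_size - M

    fail <- matrix(stats::runif(n * m) < config$detection_fail_rate, n, m)
    det <- matrix(stats::runif(n * m) * 0.001, n, m)
    det[fail] <- 0.001 + stats::runif(sum(fail)) * 0.999
  })

  dn <- list(probes$probe_id, sheet$sample_id)
  dimnames(M) <- dimnames(U) <- dimnames(det) <- dn
  out <- intensity_matrix(M, U, det)
  attr(out, "truth") <- list(baseline = stats::setNames(baseline,
                                                        probes$probe_id),
                             effect = stats::setNames(probes$effect,
                                                      probes$probe_id),
                             drift_sign = stats::setNames(probes$drift_sign,
                                                          probes$probe_id),
                             latent = `dimnames<-`(latent, dn))
  out
}

#' Simulate paired tumor/normal beta matrices with a planted signature
#'
#' Draws per-probe baseline methylation from a bimodal beta mixture; each
#' of `n_pairs` pairs contributes one normal and one tumor column. Tumor
#' columns are shifted by `delta` at the `signature_size` signature probes
#' only, with a random per-probe direction (flipped where the shift would
#' leave `[0, 1]`, then clamped); all other probes are exchangeable between
#' the two tissue classes.
#'
#' @param n_probes total probes.
#' @param n_pairs number of tumor/normal pairs (>= 2).
#' @param signature_size number of discriminating probes
#'   (<= `n_probes`).
#' @param delta tumor shift magnitude in beta units, in `[-1, 1]`.
#' @param noise_sd per-observation gaussian noise on the beta scale.
#' @param seed integer seed.
#' @param baseline_mixture as in [sim_config()].
#' @return list with `beta` (probes x 2*n_pairs matrix, columns
#'   `N01, T01, ...`), `labels` (factor `normal`/`tumor` per column) and
#'   `signature_probes` (character vector of planted probe ids).
#' @export
generate_tumor_normal <- function(n_probes, n_pairs, signature_size,
                                  delta, noise_sd, seed,
                                  baseline_mixture = list(
                                    weights = c(0.6, 0.4),
                                    means = c(0.15, 0.85),
                                    concentrations = c(15, 15))) {
  if (!is_count(n_probes) || n_probes < 1)
    stop_bad_arg("n_probes", "must be a positive count")
  if (!is_count(n_pairs) || n_pairs < 2)
    stop_bad_arg("n_pairs", "clustering needs at least 2 pairs")
  if (!is_count(signature_size) || signature_size > n_probes)
    stop_bad_arg("signature_size", "must be a count <= n_probes")
  if (!is_number(delta) || abs(delta) > 1)
    stop_bad_arg("delta", "must lie in [-1, 1]")
  if (!is_number(noise_sd) || noise_sd < 0)
    stop_bad_arg("noise_sd", "must be non-negative")
  probe_id <- sprintf("cg%06d", seq_len(n_probes))
  with_seed(seed, {
    bm <- baseline_mixture
    comp <- sample.int(2, n_probes, replace = TRUE, prob = bm$weights)
    baseline <- rbeta_mc(n_probes, bm$means[comp], bm$concentrations[comp])
    sig_idx <- sample.int(n_probes, signature_size)
    sgn <- sample(c(-1, 1), signature_size, replace = TRUE)
    # flip the direction where the full shift would leave [0, 1]
    out_hi <- baseline[sig_idx] + sgn * abs(delta) > 1
    out_lo <- baseline[sig_idx] + sgn * abs(delta) < 0
    sgn[out_hi] <- -1
    sgn[out_lo] <- 1
    shift <- numeric(n_probes)
    shift[sig_idx] <- sgn * abs(delta)

    m <- 2L * n_pairs
    beta <- matrix(baseline, n_probes, m)
    tumor_col <- seq(2, m, by = 2)
    beta[, tumor_col] <- beta[, tumor_col] + shift
    if (noise_sd > 0)
      beta <- beta + matrix(stats::rnorm(n_probes * m, 0, noise_sd),
                            n_probes, m)
    beta <- clamp(beta, 0, 1)
  })
  cols <- as.vector(rbind(sprintf("N%02d", seq_len(n_pairs)),
                          sprintf("T%02d", seq_len(n_pairs))))
  dimnames(beta) <- list(probe_id, cols)
  labels <- factor(rep(c("normal", "tumor"), n_pairs),
                   levels = c("normal", "tumor"))
  names(labels) <- cols
  list(beta = beta, labels = labels,
       signature_probes = probe_id[sort(sig_idx)])
}
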