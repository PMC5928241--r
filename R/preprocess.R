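#' QC thresholds for intensity-to-beta preprocessing
#'
#' Defaults follow standard 450K-style quality control: datapoints with
#' detection p > 0.001 are masked; probes missing in more than 10% of
#' samples are dropped; samples are dropped when their probe detection call
#' rate falls below 95%, their average signal below 2,000 AU, or below 50%
#' of the experiment-wide sample median intensity. All boundary comparisons
#' are strict, exactly as stated.
#'
#' @param detection_alpha per-datapoint detection cutoff, in (0, 1).
#' @param probe_missing_frac maximum missing fraction per probe.
#' @param sample_call_rate minimum probe detection call rate per sample.
#' @param sample_min_intensity minimum average signal per sample (AU).
#' @param sample_median_frac minimum fraction of the experiment-wide
#'   median of per-sample average intensities.
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(detection_alpha = 0.001,
                          probe_missing_frac = 0.10,
                          sample_call_rate = 0.95,
                          sample_min_intensity = 2000,
                          sample_median_frac = 0.50) {
  if (!is_number(detection_alpha) || detection_alpha <= 0 ||
      detection_alpha >= 1)
    stop_bad_arg("detection_alpha", "must lie in (0, 1)")
  check_fraction(probe_missing_frac, "probe_missing_frac")
  check_fraction(sample_call_rate, "sample_call_rate")
  check_fraction(sample_median_frac, "sample_median_frac")
  if (!is_number(sample_min_intensity) || sample_min_intensity < 0)
    stop_bad_arg("sample_min_intensity", "must be non-negative")
  structure(list(detection_alpha = detection_alpha,
                 probe_missing_frac = probe_missing_frac,
                 sample_call_rate = sample_call_rate,
                 sample_min_intensity = sample_min_intensity,
                 sample_median_frac = sample_median_frac),
            class = "qc_thresholds")
}

#' Quantile-normalize methylated and unmethylated signals together
#'
#' For each sample, the stacked vector of its M and U signals is replaced
#' so that every sample shares an identical sorted distribution (the
#' across-sample mean of order statistics), preserving within-sample ranks
#' and the per-probe M/U pairing. Detection p-values pass through
#' untouched.
#'
#' @param x an [intensity_matrix()] with at least two samples.
#' @return a normalized [intensity_matrix()].
#' @export
quantile_normalize_signals <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (ncol(x$M) < 2)
    stop("quantile normalization needs at least 2 samples", call. = FALSE)
  if (any(x$M < 0) || any(x$U < 0))
    stop("signals must be non-negative", call. = FALSE)
  p <- nrow(x$M)
  stacked <- rbind(x$M, x$U)
  norm <- limma::normalizeQuantiles(stacked, ties = TRUE)
  M <- norm[seq_len(p), , drop = FALSE]
  U <- norm[p + seq_len(p), , drop = FALSE]
  dimnames(M) <- dimnames(U) <- dimnames(x$M)
  intensity_matrix(M, U, x$detection_p)
}

#' Compute beta values from intensities
#'
#' Elementwise `beta = M / (M + U)`; datapoints with `M + U = 0` are
#' undefined and set to missing. No stabilizing offset is applied.
#'
#' @param x an [intensity_matrix()].
#' @return numeric matrix of beta values in `[0, 1]` with `NA` for
#'   missing.
#' @export
compute_beta <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (any(x$M < 0) || any(x$U < 0))
    stop("signals must be non-negative", call. = FALSE)
  tot <- x$M + x$U
  beta <- x$M / tot
  beta[tot == 0] <- NA_real_
  beta
}

#' Mask datapoints that failed detection
#'
#' Sets to missing every beta value whose detection p-value exceeds
#' `detection_alpha` (strictly); all other values are untouched.
#'
#' @param beta beta matrix.
#' @param detection_p detection p-value matrix with identical dimensions.
#' @param thresholds a [qc_thresholds()] object.
#' @return the masked beta matrix.
#' @export
mask_detection_failures <- function(beta, detection_p,
                                    thresholds = qc_thresholds()) {
  if (!identical(dim(beta), dim(detection_p)))
    stop("beta and detection_p dimensions differ", call. = FALSE)
  beta[detection_p > thresholds$detection_alpha] <- NA_real_
  beta
}

#' Remove probes with excessive missing data
#'
#' Drops probes whose missing fraction across samples strictly exceeds
#' `probe_missing_frac`; surviving values are unchanged.
#'
#' @param beta (masked) beta matrix.
#' @param thresholds a [qc_thresholds()] object.
#' @return list with `beta` (retained probes) and `removed_probes`
#'   (character vector of dropped probe ids).
#' @export
filter_probes <- function(beta, thresholds = qc_thresholds()) {
  miss <- rowMeans(is.na(beta))
  drop <- miss > thresholds$probe_missing_frac
  list(beta = beta[!drop, , drop = FALSE],
       removed_probes = rownames(beta)[drop] %||% which(drop))
}

#' Remove low-quality samples
#'
#' A sample is excluded when it fails ANY of: probe detection call rate
#' (fraction of probes with detection p <= `detection_alpha`) below
#' `sample_call_rate`; average signal intensity (mean over probes of
#' `(M + U) / 2`) below `sample_min_intensity` AU; or average intensity
#' below `sample_median_frac` of the experiment-wide median of per-sample
#' averages. All three criteria are computed from the raw (pre-masking)
#' intensity tables.
#'
#' @param x the raw [intensity_matrix()].
#' @param beta beta matrix whose columns (samples) are to be filtered.
#' @param thresholds a [qc_thresholds()] object.
#' @return list with `beta` (surviving samples) and `report`, a data.frame
#'   of per-sample call rate, average intensity, fraction of the median,
#'   per-rule failure flags and the exclusion decision.
#' @export
filter_samples <- function(x, beta, thresholds = qc_thresholds()) {
  stopifnot(inherits(x, "intensity_matrix"))
  samples <- colnames(beta)
  if (!all(samples %in% colnames(x$M)))
    stop("beta samples missing from the intensity matrix", call. = FALSE)
  call_rate <- colMeans(x$detection_p[, samples, drop = FALSE] <=
                          thresholds$detection_alpha)
  avg_int <- colMeans((x$M[, samples, drop = FALSE] +
                         x$U[, samples, drop = FALSE]) / 2)
  med <- stats::median(avg_int)
  report <- data.frame(
    sample_id = samples,
    call_rate = call_rate,
    avg_intensity = avg_int,
    frac_of_median = avg_int / med,
    fail_call_rate = call_rate < thresholds$sample_call_rate,
    fail_min_intensity = avg_int < thresholds$sample_min_intensity,
    fail_median_frac = avg_int < thresholds$sample_median_frac * med,
    row.names = NULL, stringsAsFactors = FALSE
  )
  report$excluded <- report$fail_call_rate | report$fail_min_intensity |
    report$fail_median_frac
  if (all(report$excluded)) {
    stop("all samples excluded by QC; inspect the report:\n",
         paste(utils::capture.output(print(report)), collapse = "\n"),
         call. = FALSE)
  }
  list(beta = beta[, !report$excluded, drop = FALSE], report = report)
}

#' Per-sample mean methylation
#'
#' Arithmetic mean beta over non-missing probes for each sample; samples
#' with no evaluable probe get `NA` with a warning.
#'
#' @param beta beta matrix.
#' @return named numeric vector of per-sample means.
#' @export
mean_sample_methylation <- function(beta) {
  m <- colMeans(beta, na.rm = TRUE)
  all_miss <- colSums(!is.na(beta)) == 0
  if (any(all_miss)) {
    m[all_miss] <- NA_real_
    warning("samples with all-missing beta: ",
            paste(colnames(beta)[all_miss], collapse = ", "), call. = FALSE)
  }
  m
}

#' Run the full preprocessing chain
#'
#' Fixed order: quantile normalization of the stacked M/U signals, beta
#' computation, detection masking, probe filtering, then sample filtering
#' (the sample criteria use the raw intensities). Re-running the filters on
#' already-filtered output changes nothing.
#'
#' @param x raw [intensity_matrix()].
#' @param thresholds a [qc_thresholds()] object.
#' @return list with `beta` (the QC'd matrix), `removed_probes`,
#'   `sample_report`, and `n` (per-stage probe/sample bookkeeping).
#' @export
preprocess_pipeline <- function(x, thresholds = qc_thresholds()) {
  norm <- quantile_normalize_signals(x)
  beta <- compute_beta(norm)
  beta <- mask_detection_failures(beta, norm$detection_p, thresholds)
  pf <- filter_probes(beta, thresholds)
  sf <- filter_samples(x, pf$beta, thresholds)
  list(beta = sf$beta,
       removed_probes = pf$removed_probes,
       sample_report = sf$report,
       n = list(probes_in = nrow(x$M),
                probes_removed = length(pf$removed_probes),
                probes_out = nrow(sf$beta),
                samples_in = ncol(x$M),
                samples_removed = sum(sf$report$excluded),
                samples_out = ncol(sf$beta)))
}
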