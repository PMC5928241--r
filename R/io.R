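# On-disk formats: TSV for matrices (probes as rows, samples as columns,
# "NA" sentinel for missing), BED for interval annotations (0-based
# half-open; 4th column carries the state/gene id, 6th the strand), JSON
# for reports and result objects.

#' Write / read a probe-by-sample matrix as TSV
#'
#' Probes are rows (first column `probe_id`), samples are columns;
#' missing values are written as `NA`.
#'
#' @param x numeric matrix with rownames (probes) and colnames (samples).
#' @param path output path.
#' @return `write_matrix_tsv` returns `path` invisibly; `read_matrix_tsv`
#'   returns the matrix.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(probe_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a sample sheet as TSV
#'
#' @param sheet sample sheet data.frame.
#' @param path file path.
#' @return `write_sample_sheet` returns `path` invisibly;
#'   `read_sample_sheet` returns the data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write an intensity matrix as a TSV trio
#'
#' Writes `<stem>_M.tsv`, `<stem>_U.tsv` and `<stem>_detection.tsv`.
#'
#' @param x an [intensity_matrix()].
#' @param stem path stem for the three files.
#' @return the three paths, invisibly.
#' @export
write_intensities <- function(x, stem) {
  stopifnot(inherits(x, "intensity_matrix"))
  paths <- paste0(stem, c("_M.tsv", "_U.tsv", "_detection.tsv"))
  write_matrix_tsv(x$M, paths[1])
  write_matrix_tsv(x$U, paths[2])
  write_matrix_tsv(x$detection_p, paths[3])
  invisible(paths)
}

#' @rdname write_intensities
#' @export
read_intensities <- function(stem) {
  paths <- paste0(stem, c("_M.tsv", "_U.tsv", "_detection.tsv"))
  intensity_matrix(read_matrix_tsv(paths[1]), read_matrix_tsv(paths[2]),
                   read_matrix_tsv(paths[3]))
}

#' Write / read interval annotations as BED
#'
#' BED conventions: 0-based half-open intervals; column 4 holds the
#' name (gene id or chromatin state), column 5 a score placeholder,
#' column 6 the strand where applicable.
#'
#' @param df data.frame with `chrom`, `start`, `end` and optionally
#'   `name`/`state`/`gene_id` and `strand`.
#' @param path file path.
#' @return `write_bed` returns `path` invisibly; `read_bed` returns a
#'   data.frame with `chrom`, `start`, `end` and, when present, `name`
#'   and `strand`.
#' @export
write_bed <- function(df, path) {
  name <- df$name %||% df$state %||% df$gene_id %||% "."
  out <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = name, score = 0,
                    strand = df$strand %||% ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[seq_len(min(6, ncol(df)))] <-
    c("chrom", "start", "end", "name", "score", "strand")[
      seq_len(min(6, ncol(df)))]
  df$score <- NULL
  df
}

#' Export an association table as TSV
#'
#' Stable column order: probe_id, slope, se, p, holm_p, fdr_q,
#' direction, baseline_beta, tier.
#'
#' @param tab an `association_table` from [run_ewas()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(tab, path) {
  cols <- c("probe_id", "slope", "se", "p", "holm_p", "fdr_q",
            "direction", "baseline_beta", "tier")
  utils::write.table(tab[, c(cols, setdiff(names(tab), cols))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a signature test result as JSON
#'
#' Writes the observed and Monte-Carlo p-values, the null-distribution
#' summaries, M and the seed; the full null sample optionally goes to a
#' companion TSV.
#'
#' @param x a `signature_test` from [monte_carlo_signature_test()].
#' @param path JSON output path.
#' @param null_tsv optional path for the null p-value sample.
#' @return `path`, invisibly.
#' @export
write_signature_test <- function(x, path, null_tsv = NULL) {
  stopifnot(inherits(x, "signature_test"))
  jsonlite::write_json(
    list(observed_p = x$observed_p, mc_p = x$mc_p,
         null_min = x$null_min, null_median = x$null_median,
         null_max = x$null_max, k = x$k, n_resamples = x$n_resamples,
         seed = x$seed),
    path, auto_unbox = TRUE, digits = NA)
  if (!is.null(null_tsv))
    utils::write.table(data.frame(null_p = x$null_p_values), null_tsv,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
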