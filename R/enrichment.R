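#' Chromatin-compartment enrichment of an affected probe set
#'
#' For each chromatin state, builds the 2x2 table of affected probes vs
#' the rest of the universe by in-state vs not-in-state, and tests
#' enrichment with a two-sided Fisher's exact test. The odds ratio is the
#' sample odds ratio `(a*d)/(b*c)`; its 95% confidence interval uses the
#' log-OR normal approximation (Woolf), with a 0.5 continuity correction
#' applied to all cells when any cell is zero.
#'
#' @param affected character vector of affected probe ids (subset of
#'   `universe`).
#' @param universe character vector of all evaluable probe ids.
#' @param states named character vector mapping probe id to state label
#'   (must cover the universe).
#' @return data.frame with one row per state: `state`, cells `a` (affected
#'   in state), `b` (affected not in state), `c` (rest in state), `d`
#'   (rest not in state), `odds_ratio`, `ci_low`, `ci_high`, `fisher_p`.
#' @export
compartment_enrichment <- function(affected, universe, states) {
  affected <- unique(affected); universe <- unique(universe)
  if (!all(affected %in% universe))
    stop("affected probes must be a subset of the universe", call. = FALSE)
  if (length(affected) < 1)
    stop("affected set is empty", call. = FALSE)
  if (!all(universe %in% names(states)))
    stop("states must cover every universe probe", call. = FALSE)
  st_u <- states[universe]
  st_a <- states[affected]
  lev <- sort(unique(as.character(st_u)))
  n_aff <- length(affected)
  n_rest <- length(universe) - n_aff
  rows <- lapply(lev, function(s) {
    in_state_u <- sum(st_u == s)
    if (in_state_u == 0) {
      warning("state ", s, " empty in the universe; skipped", call. = FALSE)
      return(NULL)
    }
    a <- sum(st_a == s)
    b <- n_aff - a
    cc <- in_state_u - a
    d <- n_rest - cc
    tab <- matrix(c(a, b, cc, d), 2, 2)
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    or <- if (b * cc > 0) (a * d) / (b * cc) else
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    cells <- c(a, b, cc, d)
    if (any(cells == 0)) cells <- cells + 0.5
    se_log <- sqrt(sum(1 / cells))
    or_ci <- ((cells[1] * cells[4]) / (cells[2] * cells[3]))
    data.frame(state = s, a = a, b = b, c = cc, d = d,
               odds_ratio = or,
               ci_low = exp(log(or_ci) - 1.96 * se_log),
               ci_high = exp(log(or_ci) + 1.96 * se_log),
               fisher_p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average read tag density around a probe set
#'
#' Counts reads overlapping (by at least 1 bp) each `bin_width`-bp bin in
#' the window `[pos - half_window, pos + half_window)` around every probe,
#' averages the counts across probes, and normalizes to reads per million
#' mapped.
#'
#' @param reads data.frame of read intervals (`chrom`, `start`, `end`,
#'   0-based half-open), e.g. from [generate_read_intervals()].
#' @param probes data.frame with `chrom`, `pos` (1-based); must be
#'   non-empty.
#' @param half_window window half-width in bp; a multiple of `bin_width`.
#' @param bin_width bin width in bp (default 20).
#' @param total_mapped total mapped reads used for normalization
#'   (default `nrow(reads)`).
#' @return data.frame with `offset` (bin start relative to the probe
#'   position, bp) and `density` (mean reads per bin per million mapped).
#' @export
tag_density_profile <- function(reads, probes, half_window = 2000,
                                bin_width = 20,
                                total_mapped = nrow(reads)) {
  if (nrow(probes) == 0) stop("empty probe set", call. = FALSE)
  if (half_window %% bin_width != 0)
    stop_bad_arg("half_window", "must be a multiple of bin_width")
  if (!is_number(total_mapped) || total_mapped <= 0)
    stop_bad_arg("total_mapped", "must be positive")
  offsets <- seq(-half_window, half_window - bin_width, by = bin_width)
  n_bin <- length(offsets)
  counts <- matrix(0, nrow(probes), n_bin)
  pos0 <- probes$pos - 1L
  for (chr in unique(probes$chrom)) {
    pi <- which(probes$chrom == chr)
    rd <- reads[reads$chrom == chr, , drop = FALSE]
    if (nrow(rd) == 0) next
    ir_r <- IRanges::IRanges(start = rd$start + 1L, end = rd$end)
    starts <- rep(pos0[pi], each = n_bin) + rep(offsets, length(pi))
    ir_b <- IRanges::IRanges(start = starts + 1L, width = bin_width)
    cnt <- IRanges::countOverlaps(ir_b, ir_r, minoverlap = 1L)
    counts[pi, ] <- matrix(cnt, length(pi), n_bin, byrow = TRUE)
  }
  data.frame(offset = offsets,
             density = colMeans(counts) / (total_mapped / 1e6))
}
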