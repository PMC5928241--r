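#' Construct a genome annotation object
#'
#' Holds the interval annotations the pipeline consumes: CpG islands, gene
#' models and a chromatin-state segmentation. All intervals are BED-style
#' 0-based half-open `[start, end)`; probe positions elsewhere in the
#' package are 1-based and converted internally.
#'
#' @param cgi data.frame with `chrom`, `start`, `end`.
#' @param genes data.frame with `chrom`, `tss`, `tes`, `strand` (`+`/`-`),
#'   `gene_id`. `tss`/`tes` are 0-based positions; for `-` strand genes the
#'   TES coordinate is smaller than the TSS.
#' @param chromatin data.frame with `chrom`, `start`, `end`, `state`;
#'   segments must not overlap within a chromosome.
#' @return an object of class `genome_annotation`.
#' @export
genome_annotation <- function(cgi, genes, chromatin) {
  check_intervals <- function(df, nm) {
    if (!all(c("chrom", "start", "end") %in% names(df)))
      stop_bad_arg(nm, "needs chrom/start/end columns")
    if (any(df$start < 0) || any(df$end <= df$start))
      stop_bad_arg(nm, "intervals must be 0-based half-open with end > start")
  }
  check_intervals(cgi, "cgi")
  check_intervals(chromatin, "chromatin")
  if (!all(c("chrom", "tss", "tes", "strand", "gene_id") %in% names(genes)))
    stop_bad_arg("genes", "needs chrom/tss/tes/strand/gene_id columns")
  if (any(genes$tss == genes$tes))
    stop_bad_arg("genes", "TES must differ from TSS")
  if (!all(genes$strand %in% c("+", "-")))
    stop_bad_arg("genes", "strand must be '+' or '-'")
  ok_dir <- ifelse(genes$strand == "+", genes$tes > genes$tss,
                   genes$tes < genes$tss)
  if (!all(ok_dir))
    stop_bad_arg("genes", "TES must lie downstream of TSS on the gene strand")
  for (chr in unique(chromatin$chrom)) {
    seg <- chromatin[chromatin$chrom == chr, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    if (nrow(seg) > 1 && any(seg$start[-1] < seg$end[-nrow(seg)]))
      stop_bad_arg("chromatin", "segments overlap within a chromosome")
  }
  structure(list(cgi = cgi, genes = genes, chromatin = chromatin),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d CpG islands, %d genes, %d chromatin segments on %d chromosome(s)\n",
              nrow(x$cgi), nrow(x$genes), nrow(x$chromatin),
              length(unique(c(x$cgi$chrom, x$genes$chrom, x$chromatin$chrom)))))
  invisible(x)
}

# planted-truth flags: which probes respond to dose, drift with time, or
# both; weights bias the dose-probe draw toward a chromatin/CGI context
assign_truth_flags <- function(n, config, dose_weights = NULL) {
  with_seed(config$seed + 5L, {
    w <- dose_weights %||% rep(1, n)
    n_dose <- config$n_dose_probes
    n_drift <- config$n_drift_probes
    n_both <- config$n_both_probes
    dose_idx <- if (n_dose + n_both > 0)
      sample.int(n, n_dose + n_both, prob = w) else integer(0)
    both_idx <- if (n_both > 0) dose_idx[seq_len(n_both)] else integer(0)
    drift_only <- if (n_drift > 0)
      sample(setdiff(seq_len(n), dose_idx), n_drift) else integer(0)
    drift_idx <- c(both_idx, drift_only)
    sign_dose <- switch(config$effect_profile,
                        fe_like = rep(1, length(dose_idx)),
                        x_like = rep(-1, length(dose_idx)),
                        si_like = sample(c(-1, 1), length(dose_idx),
                                         replace = TRUE))
    effect <- numeric(n)
    effect[dose_idx] <- sign_dose * abs(config$dose_effect)
    drift_sign <- integer(n)
    drift_sign[drift_idx] <- sample(c(-1L, 1L), length(drift_idx),
                                    replace = TRUE)
    list(is_dose = seq_len(n) %in% dose_idx,
         is_drift = seq_len(n) %in% drift_idx,
         effect = effect, drift_sign = drift_sign)
  })
}

#' Minimal probe manifest without genomic layout
#'
#' For simulations that only exercise preprocessing and the dose/time
#' association stages, a full synthetic genome is unnecessary. This builds
#' a probe table (ids, one synthetic chromosome, evenly spaced 1-based
#' positions) with planted-truth flags drawn uniformly across probes.
#'
#' @param config a [sim_config()] object.
#' @return data.frame with `probe_id`, `chrom`, `pos`, `truth_category`
#'   (`NA`), `is_dose`, `is_drift`, `effect` (beta/Gy), `drift_sign`.
#' @export
probe_manifest <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_probes
  fl <- assign_truth_flags(n, config)
  data.frame(probe_id = sprintf("cg%06d", seq_len(n)),
             chrom = "chrS", pos = seq_len(n) * 100L,
             truth_category = NA_character_,
             is_dose = fl$is_dose, is_drift = fl$is_drift,
             effect = fl$effect, drift_sign = fl$drift_sign,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic genome annotation and matching probe manifest
#'
#' Lays out a single synthetic chromosome as a series of gene/CpG-island
#' units: each unit carries one CpG island, usually an associated gene
#' whose TSS sits in the island (promoter-CGI architecture, either strand),
#' and a gene body extending beyond the downstream shore. The chromosome is
#' tiled completely by chromatin-state segments with numeric state labels.
#' Probes are then placed so each CGI category (Island / Shore / GeneBody /
#' Other) receives its configured share, and the realized category is
#' recorded as per-probe truth. Planted dose/drift flags are assigned as in
#' [probe_manifest()], with dose probes biased toward islands and shores
#' under the `fe_like` profile and away from them otherwise.
#'
#' @param config a [sim_config()] object.
#' @param shares named numeric vector over `Island`, `Shore`, `GeneBody`,
#'   `Other`; must sum to 1.
#' @param shore_width shore width in bp (default 2000).
#' @param unit_span bp of chromosome devoted to each gene/island unit.
#' @param gene_prob probability a CpG island has an associated gene.
#' @return list with `probes` (data.frame as in [probe_manifest()], plus a
#'   realized `truth_category` of `Island`, `Shore5`, `Shore3`, `GeneBody`
#'   or `Other`) and `annotation` (a [genome_annotation()]).
#' @export
generate_probe_annotation <- function(config,
                                      shares = c(Island = 0.3, Shore = 0.3,
                                                 GeneBody = 0.2, Other = 0.2),
                                      shore_width = 2000,
                                      unit_span = 20000,
                                      gene_prob = 0.85) {
  stopifnot(inherits(config, "sim_config"))
  need <- c("Island", "Shore", "GeneBody", "Other")
  if (!all(need %in% names(shares)))
    stop_bad_arg("shares", "must name Island, Shore, GeneBody and Other")
  shares <- shares[need]
  if (abs(sum(shares) - 1) > 1e-8)
    stop_bad_arg("shares", "must sum to 1")
  n <- config$n_probes
  n_units <- max(20L, as.integer(ceiling(n / 100)))
  chrom <- "chrS"
  chrom_length <- n_units * unit_span

  with_seed(config$seed + 2L, {
    base <- (seq_len(n_units) - 1L) * unit_span
    isl_start <- base + 4000L + sample(0:500, n_units, replace = TRUE)
    isl_width <- sample(600:1400, n_units, replace = TRUE)
    isl_end <- isl_start + isl_width
    has_gene <- stats::runif(n_units) < gene_prob
    strand <- sample(c("+", "-"), n_units, replace = TRUE)
    tss <- tes <- rep(NA_integer_, n_units)
    for (i in seq_len(n_units)) {
      if (!has_gene[i]) next
      if (strand[i] == "+") {
        tss[i] <- isl_start[i] + sample(50:300, 1)
        tes[i] <- isl_end[i] + shore_width + sample(1500:4000, 1)
      } else {
        tss[i] <- isl_end[i] - sample(50:300, 1)
        tes[i] <- isl_start[i] - shore_width - sample(1000:1800, 1)
      }
    }
    cgi <- data.frame(chrom = chrom, start = isl_start, end = isl_end)
    gi <- which(has_gene)
    genes <- data.frame(chrom = chrom, tss = tss[gi], tes = tes[gi],
                        strand = strand[gi],
                        gene_id = sprintf("g%03d", seq_along(gi)),
                        stringsAsFactors = FALSE)

    # chromatin: random-length segments tiling [0, chrom_length) exactly
    seg_start <- integer(0); pos <- 0L
    while (pos < chrom_length) {
      seg_start <- c(seg_start, pos)
      pos <- pos + sample(500:3000, 1)
    }
    seg_end <- c(seg_start[-1], chrom_length)
    chromatin <- data.frame(chrom = chrom, start = seg_start, end = seg_end,
                            state = sample(as.character(1:12),
                                           length(seg_start), replace = TRUE),
                            stringsAsFactors = FALSE)
    ann <- genome_annotation(cgi, genes, chromatin)

    # largest-remainder allocation of probe counts to categories
    raw <- shares * n
    cnt <- floor(raw)
    rem <- n - sum(cnt)
    if (rem > 0) {
      extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1
    }

    place <- function(category) {
      u <- sample.int(n_units, 1)
      pos0 <- switch(category,
        Island = isl_start[u] + sample.int(isl_width[u], 1) - 1L,
        Shore = {
          side <- sample(c("L", "R"), 1)
          off <- sample.int(shore_width, 1)
          if (side == "L") isl_start[u] - off else isl_end[u] + off - 1L
        },
        GeneBody = {
          tries <- 0
          repeat {
            tries <- tries + 1
            if (has_gene[u]) {
              if (strand[u] == "+") {
                lo <- isl_end[u] + shore_width; hi <- tes[u]
              } else {
                lo <- tes[u]; hi <- isl_start[u] - shore_width
              }
              if (hi - lo > 1) break
            }
            u <- sample.int(n_units, 1)
            if (tries > 200) stop("no gene-body interval available")
          }
          lo + sample.int(hi - lo, 1) - 1L
        },
        Other = base[u] + 12000L + sample.int(6000L, 1) - 1L
      )
      as.integer(pos0)
    }

    want <- rep(names(cnt), cnt)
    pos0 <- integer(n)
    realized <- character(n)
    for (k in seq_len(n)) {
      target <- want[k]
      for (try in 1:100) {
        cand <- place(target)
        cat_k <- cgi_category_scan(cand, cgi, genes, shore_width = shore_width)
        ok <- switch(target,
                     Island = cat_k == "Island",
                     Shore = cat_k %in% c("Shore5", "Shore3"),
                     GeneBody = cat_k == "GeneBody",
                     Other = cat_k == "Other")
        if (ok) break
      }
      if (!ok) stop("failed to place a probe in category ", target)
      pos0[k] <- cand
      realized[k] <- cat_k
    }
    ord <- order(pos0)
    pos0 <- pos0[ord]; realized <- realized[ord]
  })

  weights <- switch(config$effect_profile,
    fe_like = ifelse(realized %in% c("Island", "Shore5", "Shore3"), 3, 1),
    ifelse(realized %in% c("GeneBody", "Other"), 3, 1))
  fl <- assign_truth_flags(n, config, dose_weights = weights)
  probes <- data.frame(probe_id = sprintf("cg%06d", seq_len(n)),
                       chrom = chrom, pos = pos0 + 1L,
                       truth_category = realized,
                       is_dose = fl$is_dose, is_drift = fl$is_drift,
                       effect = fl$effect, drift_sign = fl$drift_sign,
                       stringsAsFactors = FALSE)
  list(probes = probes, annotation = ann)
}

#' Simulate mapped-read intervals around target regions
#'
#' Places single-end read start positions uniformly along a chromosome,
#' with an `enrichment`-fold excess of starts inside the target intervals
#' (ChIP-style pull-down surrogate). `enrichment = 1` is a uniform,
#' input-like track.
#'
#' @param targets data.frame with `chrom`, `start`, `end` (0-based
#'   half-open); may be empty when `enrichment = 1`.
#' @param n_reads number of reads to draw.
#' @param enrichment fold excess of start density inside targets (>= 1).
#' @param read_length read length in bp (> 0).
#' @param chrom_length chromosome length in bp.
#' @param seed integer seed.
#' @return data.frame of read intervals `chrom`, `start`, `end` (0-based
#'   half-open, width `read_length`).
#' @export
generate_read_intervals <- function(targets, n_reads, enrichment = 1,
                                    read_length = 50, chrom_length,
                                    seed) {
  if (!is_count(n_reads) || n_reads < 1)
    stop_bad_arg("n_reads", "must be a positive count")
  if (!is_number(enrichment) || enrichment < 1)
    stop_bad_arg("enrichment", "must be >= 1")
  if (!is_number(read_length) || read_length <= 0)
    stop_bad_arg("read_length", "must be positive")
  if (!is_count(chrom_length) || chrom_length < 1)
    stop_bad_arg("chrom_length", "must be a positive count")
  chrom <- if (nrow(targets) > 0) targets$chrom[1] else "chrS"
  t_len <- if (nrow(targets) > 0) sum(targets$end - targets$start) else 0
  bg_len <- chrom_length - t_len
  w_target <- enrichment * t_len / (enrichment * t_len + bg_len)
  with_seed(seed, {
    n_in <- stats::rbinom(1, n_reads, w_target)
    starts <- integer(0)
    if (n_in > 0) {
      # uniform over the concatenated target space
      widths <- targets$end - targets$start
      off <- sample.int(t_len, n_in, replace = TRUE) - 1L
      cum <- cumsum(widths)
      idx <- findInterval(off, c(0, cum), rightmost.closed = FALSE)
      starts <- targets$start[idx] + (off - c(0, cum)[idx])
    }
    if (n_reads - n_in > 0) {
      # background: uniform over the complement, by rejection
      need <- n_reads - n_in
      bg <- integer(0)
      while (length(bg) < need) {
        cand <- sample.int(chrom_length, max(need * 2, 100),
                           replace = TRUE) - 1L
        if (t_len > 0) {
          in_t <- rep(FALSE, length(cand))
          for (i in seq_len(nrow(targets)))
            in_t <- in_t | (cand >= targets$start[i] & cand < targets$end[i])
          cand <- cand[!in_t]
        }
        bg <- c(bg, cand)
      }
      starts <- c(starts, bg[seq_len(need)])
    }
    starts <- starts[sample.int(length(starts))] # shuffle interleaving
  })
  data.frame(chrom = chrom, start = as.integer(starts),
             end = as.integer(starts + read_length))
}
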