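# Probe positions are 1-based (array-manifest convention); all annotation
# intervals are 0-based half-open. Conversion happens here, once.

# distance from a 0-based point to a 0-based half-open interval, plus side
point_interval_distance <- function(pos0, s, e) {
  ifelse(pos0 < s, s - pos0, ifelse(pos0 >= e, pos0 - e + 1L, 0L))
}

# strand orientation of each island: the strand of the gene whose TSS is
# nearest the island (ties to the smaller gene_id); islands with no gene
# within max_gene_dist fall back to genomic orientation ("+", left = 5')
island_orientation <- function(cgi, genes, max_gene_dist = 10000) {
  n <- nrow(cgi)
  strand <- rep("+", n)
  gene_idx <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    g <- which(genes$chrom == cgi$chrom[i])
    if (!length(g)) next
    d <- point_interval_distance(genes$tss[g], cgi$start[i], cgi$end[i])
    cand <- g[d == min(d)]
    if (min(d) > max_gene_dist) next
    cand <- cand[order(genes$gene_id[cand])][1]
    strand[i] <- genes$strand[cand]
    gene_idx[i] <- cand
  }
  list(strand = strand, gene_idx = gene_idx)
}

# gene-body intervals (0-based half-open) implied by island/gene pairs:
# from the downstream-shore edge of the promoter island to the TES
island_body_intervals <- function(cgi, genes, shore_width = 2000,
                                  max_gene_dist = 10000) {
  ori <- island_orientation(cgi, genes, max_gene_dist)
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0))
  for (i in seq_len(nrow(cgi))) {
    gi <- ori$gene_idx[i]
    if (is.na(gi)) next
    if (genes$strand[gi] == "+") {
      s <- cgi$end[i] + shore_width; e <- genes$tes[gi]
    } else {
      s <- genes$tes[gi]; e <- cgi$start[i] - shore_width
    }
    if (e > s)
      out <- rbind(out, data.frame(chrom = cgi$chrom[i], start = s, end = e))
  }
  out
}

# naive single-position categorizer used by the simulator to verify probe
# placement; assign_cgi_category() is the vectorized production path
cgi_category_scan <- function(pos0, cgi, genes, shore_width = 2000,
                              max_gene_dist = 10000) {
  inside <- cgi$start <= pos0 & pos0 < cgi$end
  if (any(inside)) return("Island")
  if (nrow(cgi)) {
    d <- point_interval_distance(pos0, cgi$start, cgi$end)
    i <- which.min(d)
    if (d[i] <= shore_width) {
      ori <- island_orientation(cgi[i, , drop = FALSE], genes, max_gene_dist)
      left <- pos0 < cgi$start[i]
      if (ori$strand == "+") return(if (left) "Shore5" else "Shore3")
      return(if (left) "Shore3" else "Shore5")
    }
  }
  body <- island_body_intervals(cgi, genes, shore_width, max_gene_dist)
  if (nrow(body) && any(body$start <= pos0 & pos0 < body$end))
    return("GeneBody")
  "Other"
}

#' Categorize probes by CpG island context
#'
#' Assigns each probe exactly one category with precedence Island >
#' Shore > GeneBody > Other: probes overlapping a CpG island are
#' `Island`; probes within `shore_width` bp of the nearest island's edge
#' are shores, with 5'/3' resolved by the strand of the island-associated
#' gene (the gene whose TSS lies nearest the island, within
#' `max_gene_dist`; islands with no such gene use genomic orientation,
#' left = 5'); probes between an island's downstream shore edge and the
#' associated gene's transcription end site are `GeneBody`; everything
#' else is `Other`.
#'
#' @param probes data.frame with `probe_id`, `chrom`, `pos` (1-based).
#' @param annotation a [genome_annotation()].
#' @param shore_width shore width in bp (default 2000).
#' @param max_gene_dist maximum TSS-to-island distance for gene
#'   association (default 10000).
#' @return character vector of categories, one per probe (`Island`,
#'   `Shore5`, `Shore3`, `GeneBody`, `Other`).
#' @export
assign_cgi_category <- function(probes, annotation, shore_width = 2000,
                                max_gene_dist = 10000) {
  stopifnot(inherits(annotation, "genome_annotation"))
  out <- rep("Other", nrow(probes))
  pos0 <- probes$pos - 1L
  body <- island_body_intervals(annotation$cgi, annotation$genes,
                                shore_width, max_gene_dist)
  for (chr in unique(probes$chrom)) {
    pi <- which(probes$chrom == chr)
    cgi <- annotation$cgi[annotation$cgi$chrom == chr, , drop = FALSE]
    if (nrow(cgi) == 0) {
      warning("no islands on chromosome ", chr,
              "; probes there assigned 'Other'", call. = FALSE)
      next
    }
    ir_p <- IRanges::IRanges(start = pos0[pi] + 1L, width = 1L)
    ir_i <- IRanges::IRanges(start = cgi$start + 1L, end = cgi$end)
    cat_chr <- rep("Other", length(pi))
    cat_chr[IRanges::overlapsAny(ir_p, ir_i)] <- "Island"

    ori <- island_orientation(cgi, annotation$genes, max_gene_dist)
    dtn <- IRanges::distanceToNearest(ir_p, ir_i)
    hit <- S4Vectors::queryHits(dtn)
    isl <- S4Vectors::subjectHits(dtn)
    gap <- S4Vectors::mcols(dtn)$distance
    shore <- cat_chr[hit] != "Island" & gap + 1L <= shore_width
    left <- pos0[pi][hit] < cgi$start[isl]
    lab <- ifelse(ori$strand[isl] == "+",
                  ifelse(left, "Shore5", "Shore3"),
                  ifelse(left, "Shore3", "Shore5"))
    cat_chr[hit[shore]] <- lab[shore]

    bd <- body[body$chrom == chr, , drop = FALSE]
    if (nrow(bd)) {
      ir_b <- IRanges::IRanges(start = bd$start + 1L, end = bd$end)
      in_body <- IRanges::overlapsAny(ir_p, ir_b)
      cat_chr[in_body & cat_chr == "Other"] <- "GeneBody"
    }
    out[pi] <- cat_chr
  }
  out
}

# nearest-TSS lookup shared by signed_tss_distance() and nearest_gene();
# ties broken toward the smaller gene id
nearest_tss_core <- function(probes, genes) {
  n <- nrow(probes)
  gene_id <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  pos0 <- probes$pos - 1L
  for (chr in unique(probes$chrom)) {
    pi <- which(probes$chrom == chr)
    g <- genes[genes$chrom == chr, , drop = FALSE]
    if (nrow(g) == 0) {
      warning("no genes on chromosome ", chr, call. = FALSE)
      next
    }
    g <- g[order(g$gene_id), , drop = FALSE]
    for (k in pi) {
      ad <- abs(pos0[k] - g$tss)
      j <- which.min(ad) # first index = smallest gene_id on ties
      gene_id[k] <- g$gene_id[j]
      dist[k] <- if (g$strand[j] == "+") pos0[k] - g$tss[j]
                 else g$tss[j] - pos0[k]
    }
  }
  list(gene_id = gene_id, distance = dist)
}

#' Signed distance to the nearest transcription start site
#'
#' Distance in bp from each probe to the nearest TSS, oriented to the
#' direction of transcription: positive downstream of the TSS, negative
#' upstream. Ties between equidistant TSSs go to the smaller gene id.
#'
#' @param probes data.frame with `chrom`, `pos` (1-based).
#' @param genes gene table as in [genome_annotation()].
#' @return numeric vector of signed distances (NA where the chromosome
#'   has no gene).
#' @export
signed_tss_distance <- function(probes, genes) {
  nearest_tss_core(probes, genes)$distance
}

#' Nearest gene per probe
#'
#' @inheritParams signed_tss_distance
#' @return character vector of gene ids (ties as in
#'   [signed_tss_distance()]).
#' @export
nearest_gene <- function(probes, genes) {
  nearest_tss_core(probes, genes)$gene_id
}

#' Overlap counts between two probe or gene sets
#'
#' @param a,b character vectors (duplicates ignored).
#' @return named integer vector `both`, `a_only`, `b_only`.
#' @export
set_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  c(both = length(intersect(a, b)),
    a_only = length(setdiff(a, b)),
    b_only = length(setdiff(b, a)))
}

#' Island-scaled meta-coordinate of a probe
#'
#' Maps each probe to a common coordinate system around its nearest CpG
#' island: positions inside the island are the fractional distance from
#' the 5' edge (0 at the 5' edge, 1 at the 3' edge), the 5' flank is the
#' negative distance in bp from the 5' edge, and the 3' flank is 1 plus
#' the distance in bp beyond the 3' edge. 5'/3' follow the
#' island-associated gene's strand as in [assign_cgi_category()]. Probes
#' farther than `profile_flank` from the island get `NA`.
#'
#' @param probes data.frame with `chrom`, `pos` (1-based).
#' @param annotation a [genome_annotation()].
#' @param profile_flank flank width in bp (default 2500).
#' @param max_gene_dist as in [assign_cgi_category()].
#' @return numeric vector of scaled coordinates.
#' @export
scaled_island_coordinate <- function(probes, annotation,
                                     profile_flank = 2500,
                                     max_gene_dist = 10000) {
  stopifnot(inherits(annotation, "genome_annotation"))
  cgi_all <- annotation$cgi
  if (any(cgi_all$end - cgi_all$start <= 0))
    stop("zero-width CpG island in annotation", call. = FALSE)
  out <- rep(NA_real_, nrow(probes))
  pos0 <- probes$pos - 1L
  for (chr in unique(probes$chrom)) {
    pi <- which(probes$chrom == chr)
    cgi <- cgi_all[cgi_all$chrom == chr, , drop = FALSE]
    if (nrow(cgi) == 0) next
    ori <- island_orientation(cgi, annotation$genes, max_gene_dist)
    for (k in pi) {
      d <- point_interval_distance(pos0[k], cgi$start, cgi$end)
      i <- which.min(d)
      s <- cgi$start[i]; e <- cgi$end[i]; w <- e - s
      plus <- ori$strand[i] == "+"
      if (s <= pos0[k] && pos0[k] <= e) {
        out[k] <- if (plus) (pos0[k] - s) / w else (e - pos0[k]) / w
      } else if (pos0[k] < s) {
        g <- s - pos0[k]
        if (g <= profile_flank) out[k] <- if (plus) -g else 1 + g
      } else {
        g <- pos0[k] - e
        if (g <= profile_flank) out[k] <- if (plus) 1 + g else -g
      }
    }
  }
  out
}

#' Default chromatin-state merge table
#'
#' Merges the two strong-enhancer states (4, 5), the two weak-enhancer
#' states (6, 7), and the transcription-associated states (9, 10, 11,
#' i.e. transition, elongation and weak transcription) into single
#' labels; all other states keep their raw labels.
#'
#' @return named character vector mapping raw state labels to merged
#'   labels.
#' @export
default_state_merge <- function() {
  c("4" = "Strong Enhancer", "5" = "Strong Enhancer",
    "6" = "Weak Enhancer", "7" = "Weak Enhancer",
    "9" = "Transcribed Regions", "10" = "Transcribed Regions",
    "11" = "Transcribed Regions")
}

#' Assign probes to (merged) chromatin states
#'
#' Looks up the chromatin-state segment containing each probe and maps the
#' raw state label through the merge table. Probes falling in no segment
#' get `Unassigned` with a warning.
#'
#' @param probes data.frame with `chrom`, `pos` (1-based).
#' @param segments chromatin segment table (`chrom`, `start`, `end`,
#'   `state`) or a [genome_annotation()].
#' @param merge_map named character vector; see [default_state_merge()].
#' @return character vector of state labels.
#' @export
assign_chromatin_state <- function(probes, segments,
                                   merge_map = default_state_merge()) {
  if (inherits(segments, "genome_annotation")) segments <- segments$chromatin
  out <- rep(NA_character_, nrow(probes))
  pos0 <- probes$pos - 1L
  for (chr in unique(probes$chrom)) {
    pi <- which(probes$chrom == chr)
    seg <- segments[segments$chrom == chr, , drop = FALSE]
    if (nrow(seg) == 0) next
    ir_p <- IRanges::IRanges(start = pos0[pi] + 1L, width = 1L)
    ir_s <- IRanges::IRanges(start = seg$start + 1L, end = seg$end)
    ov <- IRanges::findOverlaps(ir_p, ir_s, select = "first")
    out[pi] <- as.character(seg$state)[ov]
  }
  if (anyNA(out)) {
    warning(sum(is.na(out)), " probe(s) in no chromatin segment;",
            " assigned 'Unassigned'", call. = FALSE)
    out[is.na(out)] <- "Unassigned"
  }
  mapped <- unname(merge_map[out])
  ifelse(is.na(mapped), out, mapped)
}
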