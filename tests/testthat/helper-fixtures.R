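# Shared fixtures and independent oracles, built in code at test time.

# small exposure config: 4 doses x 4 times x 3 reps, no planted effects
# unless overridden
small_config <- function(n_probes = 50, seed = 101, ...) {
  args <- utils::modifyList(
    list(n_probes = n_probes, n_dose_probes = 0, n_drift_probes = 0,
         detection_fail_rate = 0, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# hand-built annotation on one chromosome:
#   island A [10000, 11000) with + strand gene gA (tss 10100, tes 15000)
#   island B [30000, 30800) with - strand gene gB (tss 30700, tes 26000)
#   island C [50000, 50400) with no gene within 10 kb
toy_annotation <- function() {
  genome_annotation(
    cgi = data.frame(chrom = "chr1",
                     start = c(10000L, 30000L, 50000L),
                     end = c(11000L, 30800L, 50400L)),
    genes = data.frame(chrom = "chr1",
                       tss = c(10100L, 30700L),
                       tes = c(15000L, 26000L),
                       strand = c("+", "-"),
                       gene_id = c("gA", "gB"),
                       stringsAsFactors = FALSE),
    chromatin = data.frame(chrom = "chr1",
                           start = seq(0L, 59000L, by = 1000L),
                           end = seq(1000L, 60000L, by = 1000L),
                           state = as.character(rep(1:12, 5)),
                           stringsAsFactors = FALSE))
}

probes_at <- function(pos, chrom = "chr1") {
  data.frame(probe_id = sprintf("p%03d", seq_along(pos)),
             chrom = chrom, pos = as.integer(pos),
             stringsAsFactors = FALSE)
}

# --- independent oracles -------------------------------------------------

holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# OLS by explicit normal equations (independent of lm/qr paths)
ols_oracle <- function(y, X, term) {
  XtX <- t(X) %*% X
  bhat <- solve(XtX, t(X) %*% y)
  res <- y - X %*% bhat
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  covb <- sigma2 * solve(XtX)
  j <- match(term, colnames(X))
  est <- bhat[j]
  se <- sqrt(covb[j, j])
  list(slope = est, se = se, p = 2 * pt(-abs(est / se), df = df))
}

# two-sided Fisher p by hypergeometric enumeration
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0, k - n):min(k, m)
  dens <- dhyper(x, m, n, k)
  sum(dens[dens <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

# naive O(n^3) agglomerative complete linkage, cut at k clusters
complete_linkage_oracle <- function(D, k = 2) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    m <- length(clusters)
    best <- Inf; bi <- bj <- NA
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      d <- max(D[clusters[[i]], clusters[[j]]])
      if (d < best) { best <- d; bi <- i; bj <- j }
    }
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  lab <- integer(n)
  for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
  # renumber by first occurrence so labels are comparable
  as.integer(factor(lab, levels = unique(lab)))
}

# naive per-probe CGI categorizer following the documented rules
cgi_oracle <- function(pos1, ann, shore_width = 2000,
                       max_gene_dist = 10000) {
  cgi <- ann$cgi; genes <- ann$genes
  pos0 <- pos1 - 1
  pid <- function(p, s, e) if (p < s) s - p else if (p >= e) p - e + 1 else 0
  if (any(cgi$start <= pos0 & pos0 < cgi$end)) return("Island")
  d <- vapply(seq_len(nrow(cgi)),
              function(i) pid(pos0, cgi$start[i], cgi$end[i]), numeric(1))
  ni <- which.min(d)
  strand_of <- function(i) {
    gd <- vapply(seq_len(nrow(genes)),
                 function(g) pid(genes$tss[g], cgi$start[i], cgi$end[i]),
                 numeric(1))
    if (!length(gd) || min(gd) > max_gene_dist) return("+")
    cand <- which(gd == min(gd))
    genes$strand[cand[order(genes$gene_id[cand])][1]]
  }
  if (d[ni] <= shore_width) {
    left <- pos0 < cgi$start[ni]
    if (strand_of(ni) == "+") return(if (left) "Shore5" else "Shore3")
    return(if (left) "Shore3" else "Shore5")
  }
  for (i in seq_len(nrow(cgi))) {
    gd <- vapply(seq_len(nrow(genes)),
                 function(g) pid(genes$tss[g], cgi$start[i], cgi$end[i]),
                 numeric(1))
    if (!length(gd) || min(gd) > max_gene_dist) next
    cand <- which(gd == min(gd))
    g <- cand[order(genes$gene_id[cand])][1]
    if (genes$strand[g] == "+") {
      s <- cgi$end[i] + shore_width; e <- genes$tes[g]
    } else {
      s <- genes$tes[g]; e <- cgi$start[i] - shore_width
    }
    if (e > s && pos0 >= s && pos0 < e) return("GeneBody")
  }
  "Other"
}
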