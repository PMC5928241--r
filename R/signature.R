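#' Filter probes by detection quality across a sample set
#'
#' Retains probes whose detection p-value is at or below `alpha` in every
#' sample. The same rule defines the universe from which random probe
#' sets are drawn in [monte_carlo_signature_test()].
#'
#' @param beta beta matrix (probes x samples).
#' @param detection_p detection p-value matrix with identical dimensions.
#' @param alpha per-datapoint detection cutoff (default 0.05).
#' @return character vector of retained probe ids.
#' @export
filter_signature_probes <- function(beta, detection_p, alpha = 0.05) {
  if (!identical(dim(beta), dim(detection_p)))
    stop("beta and detection_p dimensions differ", call. = FALSE)
  keep <- rowSums(detection_p > alpha) == 0
  if (!any(keep))
    stop("no probe passes the detection filter", call. = FALSE)
  (rownames(beta) %||% as.character(seq_len(nrow(beta))))[keep]
}

#' Manhattan distance matrix between samples
#'
#' `d(i, j) = sum over probes of |beta[p, i] - beta[p, j]|`.
#'
#' @param beta beta matrix (probes x samples) without missing values;
#'   apply [filter_signature_probes()] first.
#' @return symmetric samples x samples distance matrix with zero
#'   diagonal.
#' @export
manhattan_distance_matrix <- function(beta) {
  if (anyNA(beta))
    stop("beta contains missing values; filter probes first (see ",
         "filter_signature_probes)", call. = FALSE)
  as.matrix(stats::dist(t(beta), method = "manhattan"))
}

#' Cut an agglomerative complete-linkage tree at k clusters
#'
#' Hierarchical clustering with complete (maximum) linkage, cut to
#' exactly `k` clusters. Cluster labels are renumbered by first
#' occurrence, so the labeling is deterministic given the distances.
#'
#' @param distances a `dist` object or symmetric distance matrix.
#' @param k number of clusters (default 2; must not exceed the sample
#'   count).
#' @return integer vector of cluster labels in `1..k`.
#' @export
complete_linkage_cut <- function(distances, k = 2) {
  d <- stats::as.dist(distances)
  n <- attr(d, "Size")
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  cl <- stats::cutree(stats::hclust(d, method = "complete"), k = k)
  # renumber by first occurrence
  as.integer(factor(cl, levels = unique(cl)))
}

#' Chi-square association between cluster and tissue labels
#'
#' Pearson chi-square (1 df, no continuity correction by default) on the
#' 2x2 contingency of cluster membership by tissue class. A degenerate
#' margin (an empty cluster or class) yields p = 1 with a flag.
#'
#' @param clusters cluster labels (two clusters).
#' @param labels tissue labels (two classes).
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return list with `statistic`, `p_value`, `table`, `flag` (`NA` or
#'   `"degenerate_margin"`).
#' @export
cluster_label_association <- function(clusters, labels, correct = FALSE) {
  tab <- table(cluster = clusters, label = labels)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) ||
      nrow(tab) < 2 || ncol(tab) < 2) {
    return(list(statistic = NA_real_, p_value = 1, table = tab,
                flag = "degenerate_margin"))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       table = tab, flag = NA_character_)
}

#' Monte-Carlo test of a methylation signature's discriminating power
#'
#' Tests whether a fixed probe signature separates two tissue classes
#' (e.g. tumor vs normal) better than random probe sets of the same size.
#' The observed statistic is the chi-square association p-value between
#' the k = 2 complete-linkage/Manhattan clustering of the signature's beta
#' values and the tissue labels. The null distribution is built by
#' drawing `n_resamples` probe sets of the same size, uniformly without
#' replacement from `pool_probes`, and recomputing the same clustering
#' association p-value. The Monte-Carlo p-value uses the add-one
#' estimator `(1 + #[null p <= observed p]) / (n_resamples + 1)`, so it is
#' never zero.
#'
#' When the planted signal is strong, resampled sets that contain many
#' signature probes can themselves separate the classes perfectly and tie
#' the observed p-value; supply a `pool_probes` that excludes the
#' signature to test it against a strictly null background.
#'
#' @param beta beta matrix (probes x samples), no missing values among
#'   the pool and signature probes.
#' @param labels two-class tissue labels per sample.
#' @param signature_probes character vector of signature probe ids.
#' @param pool_probes probe ids to resample from (default: all rows of
#'   `beta`); must be at least as large as the signature.
#' @param n_resamples number of random draws M (default 1000).
#' @param seed integer seed for the resampling.
#' @param k number of clusters for the dendrogram cut (default 2).
#' @param correct Yates correction flag, see
#'   [cluster_label_association()].
#' @return object of class `signature_test`: list with `observed_p`,
#'   `mc_p`, `null_p_values` (length M), `null_min`, `null_median`,
#'   `null_max`, `k`, `n_resamples`, `seed`, `clusters` (the observed
#'   signature clustering).
#' @export
monte_carlo_signature_test <- function(beta, labels, signature_probes,
                                       pool_probes = rownames(beta),
                                       n_resamples = 1000, seed,
                                       k = 2, correct = FALSE) {
  if (missing(seed)) stop_bad_arg("seed", "a seed is mandatory")
  if (!is_count(n_resamples) || n_resamples < 1)
    stop_bad_arg("n_resamples", "must be a positive count")
  if (!all(signature_probes %in% rownames(beta)) ||
      !all(pool_probes %in% rownames(beta)))
    stop("signature and pool probes must be rows of beta", call. = FALSE)
  if (length(pool_probes) < length(signature_probes))
    stop("pool must be at least as large as the signature", call. = FALSE)
  if (anyNA(beta[union(signature_probes, pool_probes), , drop = FALSE]))
    stop("beta contains missing values among signature/pool probes; ",
         "filter probes first (see filter_signature_probes)", call. = FALSE)
  cluster_p <- function(ids) {
    cl <- complete_linkage_cut(
      stats::dist(t(beta[ids, , drop = FALSE]), method = "manhattan"), k)
    cluster_label_association(cl, labels, correct)
  }
  obs <- cluster_p(signature_probes)
  m <- length(signature_probes)
  null_p <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      cluster_p(sample(pool_probes, m))$p_value
    }, numeric(1))
  })
  structure(list(
    observed_p = obs$p_value,
    mc_p = (1 + sum(null_p <= obs$p_value)) / (n_resamples + 1),
    null_p_values = null_p,
    null_min = min(null_p), null_median = stats::median(null_p),
    null_max = max(null_p),
    k = k, n_resamples = n_resamples, seed = as.integer(seed),
    clusters = {
      cl <- complete_linkage_cut(
        stats::dist(t(beta[signature_probes, , drop = FALSE]),
                    method = "manhattan"), k)
      stats::setNames(cl, colnames(beta))
    }
  ), class = "signature_test")
}

#' @export
print.signature_test <- function(x, ...) {
  cat(sprintf("<signature_test> observed chi-square p = %.3g\n",
              x$observed_p))
  cat(sprintf("  Monte-Carlo p = %.4g (M = %d, seed %d)\n",
              x$mc_p, x$n_resamples, x$seed))
  cat(sprintf("  null p range %.4g-%.4g; median %.4g\n",
              x$null_min, x$null_max, x$null_median))
  invisible(x)
}
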