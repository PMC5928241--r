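#' Build the per-probe regression design from a sample sheet
#'
#' Dose (Gy) and time (days) enter as numeric covariates; chip row is
#' categorical; chip is the grouping factor for the random intercept.
#'
#' @param sheet sample sheet with `dose`, `time`, `row`, `chip`.
#' @return data.frame with `dose`, `time`, `row` (factor), `chip` (factor).
#' @export
ewas_design <- function(sheet) {
  for (nm in c("dose", "time", "row", "chip"))
    if (is.null(sheet[[nm]])) stop("sample sheet lacks column ", nm,
                                   call. = FALSE)
  data.frame(dose = as.numeric(sheet$dose), time = as.numeric(sheet$time),
             row = factor(sheet$row), chip = factor(sheet$chip))
}

# fixed-effect terms actually usable given the data (factors need >1 level)
fixed_terms <- function(data) {
  c("dose", "time", if (nlevels(droplevels(data$row)) > 1) "row")
}

# shared per-design machinery reused across probes: the fixed-effect model
# matrix QR (OLS path) and a fitted lmer template for fast refits
ewas_base_fit <- function(data) {
  terms <- fixed_terms(data)
  X <- stats::model.matrix(
    stats::reformulate(terms), droplevels(data))
  qrX <- qr(X)
  mixed <- nlevels(droplevels(data$chip)) > 1
  template <- NULL
  if (mixed) {
    fml <- stats::reformulate(c(terms, "(1 | chip)"), response = "y")
    dat <- droplevels(data)
    # deterministic template response: refit() restarts the optimizer
    # from the template's estimate, so the template must not depend on
    # the global RNG state
    dat$y <- sin(seq_len(nrow(dat)))
    template <- suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = dat, REML = TRUE,
                 control = lme4::lmerControl(
                   calc.derivs = FALSE,
                   check.conv.singular = "ignore"))))
  }
  list(X = X, qr = qrX, rank = qrX$rank, n = nrow(X),
       mixed = mixed, template = template, terms = terms)
}

# exact OLS via the precomputed QR; matches lm() to machine precision
ols_stats <- function(base, y, term) {
  n <- base$n; r <- base$rank
  if (r < ncol(base$X)) return(NULL) # aliased fixed effects
  coefs <- qr.coef(base$qr, y)
  j <- match(term, colnames(base$X))
  if (is.na(j) || is.na(coefs[j])) return(NULL)
  res <- qr.resid(base$qr, y)
  sigma2 <- sum(res^2) / (n - r)
  XtX_inv <- chol2inv(qr.R(base$qr))
  se <- sqrt(sigma2 * XtX_inv[j, j])
  est <- unname(coefs[j])
  tval <- est / se
  list(slope = est, se = se,
       p = 2 * stats::pt(-abs(tval), df = n - r),
       df = n - r, method = "ols")
}

#' Fit the per-probe linear mixed model
#'
#' Models one probe's beta values as a linear function of dose and time
#' (numeric) and chip row (categorical), with a random intercept per chip,
#' by REML. Inference on the target coefficient is a two-sided Wald t-test
#' on residual degrees of freedom. When the random-intercept variance is
#' estimated at zero (a singular fit), when the fit fails, or when only one
#' chip is present, the model reduces exactly to ordinary least squares on
#' the same fixed effects. `engine = "ols"` forces the chip variance to
#' zero unconditionally.
#'
#' @param y numeric response (no missing values; drop missing samples
#'   before calling).
#' @param data design data.frame from [ewas_design()], aligned with `y`.
#' @param target_term `"dose"` or `"time"`.
#' @param engine `"auto"` (mixed model with OLS fallback) or `"ols"`.
#' @param base internal: a precomputed [ewas_base_fit] for this design.
#' @return list with `slope`, `se`, `p`, `df`, `method` (`"lmm"` or
#'   `"ols"`), `flag` (`NA` or a reason the statistics are missing).
#' @export
fit_probe_mixed_model <- function(y, data, target_term = c("dose", "time"),
                                  engine = c("auto", "ols"), base = NULL) {
  target_term <- match.arg(target_term)
  engine <- match.arg(engine)
  if (length(y) != nrow(data))
    stop("length(y) must match nrow(data)", call. = FALSE)
  if (anyNA(y))
    stop("y contains missing values; drop those samples first",
         call. = FALSE)
  empty <- list(slope = NA_real_, se = NA_real_, p = NA_real_,
                df = NA_real_, method = NA_character_)
  if (stats::sd(y) == 0) return(c(empty, flag = "constant_response"))
  if (is.null(base)) base <- ewas_base_fit(data)
  if (base$n < base$rank + 2)
    return(c(empty, flag = "too_few_observations"))
  ols <- ols_stats(base, y, target_term)
  if (is.null(ols)) return(c(empty, flag = "singular_design"))
  if (engine == "ols" || !base$mixed) return(c(ols, flag = NA_character_))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(lme4::refit(base$template, y))),
    error = function(e) NULL)
  if (is.null(fit)) return(c(ols, flag = "ols_fallback"))
  if (lme4::isSingular(fit, tol = 1e-4)) return(c(ols, flag = NA_character_))
  est <- lme4::fixef(fit)[target_term]
  se <- sqrt(as.matrix(stats::vcov(fit))[target_term, target_term])
  tval <- unname(est / se)
  list(slope = unname(est), se = unname(se),
       p = 2 * stats::pt(-abs(tval), df = base$n - base$rank),
       df = base$n - base$rank, method = "lmm", flag = NA_character_)
}

#' Epigenome-wide association of methylation with dose or time
#'
#' Fits [fit_probe_mixed_model()] to every probe of one exposure series
#' and assembles the association table: slope (beta units per Gy or per
#' day), standard error, two-sided Wald p, Holm-adjusted p,
#' Benjamini-Hochberg q, direction (hyper for positive slopes, hypo for
#' negative), baseline mean beta (mean over the 0-dose samples), and the
#' significance tier (`nominal` when the Holm-corrected p < 0.05,
#' `moderate` when the uncorrected p < 0.001, otherwise `none`).
#'
#' Samples with missing beta are dropped listwise per probe; probes with
#' fewer than `min_prop` of samples present are skipped and flagged.
#'
#' @param beta beta matrix (probes x samples), columns matching
#'   `sheet$sample_id`.
#' @param sheet sample sheet for a single exposure series.
#' @param target_term `"dose"` or `"time"`.
#' @param engine passed to [fit_probe_mixed_model()].
#' @param min_prop minimum fraction of samples a probe must retain.
#' @param nominal_alpha Holm-corrected threshold for the nominal tier.
#' @param moderate_alpha uncorrected threshold for the moderate tier.
#' @return data.frame (class `association_table`) with one row per probe:
#'   `probe_id`, `slope`, `se`, `p`, `holm_p`, `fdr_q`, `direction`,
#'   `baseline_beta`, `tier`, `n_used`, `method`, `flag`.
#' @export
run_ewas <- function(beta, sheet, target_term = c("dose", "time"),
                     engine = c("auto", "ols"), min_prop = 0.8,
                     nominal_alpha = 0.05, moderate_alpha = 0.001) {
  target_term <- match.arg(target_term)
  engine <- match.arg(engine)
  if (!is.null(colnames(beta)) && !is.null(sheet$sample_id)) {
    if (!setequal(colnames(beta), sheet$sample_id))
      stop("beta columns and sheet samples differ", call. = FALSE)
    beta <- beta[, sheet$sample_id, drop = FALSE]
  } else if (ncol(beta) != nrow(sheet)) {
    stop("beta columns and sheet rows differ in number", call. = FALSE)
  }
  data <- ewas_design(sheet)
  if (length(unique(data[[target_term]])) < 2)
    stop("target term '", target_term,
         "' has a single level in this series", call. = FALSE)
  n_probe <- nrow(beta)
  base_full <- ewas_base_fit(data)
  slope <- se <- p <- rep(NA_real_, n_probe)
  n_used <- integer(n_probe)
  method <- flag <- rep(NA_character_, n_probe)
  ok_mat <- !is.na(beta)
  base_cache <- new.env(parent = emptyenv()) # per-missing-pattern bases
  for (i in seq_len(n_probe)) {
    ok <- ok_mat[i, ]
    n_used[i] <- sum(ok)
    if (n_used[i] < min_prop * nrow(data)) {
      flag[i] <- "too_many_missing"
      next
    }
    if (all(ok)) {
      f <- fit_probe_mixed_model(beta[i, ], data, target_term, engine,
                                 base = base_full)
    } else {
      key <- paste(which(!ok), collapse = ",")
      cached <- base_cache[[key]]
      if (is.null(cached)) {
        sub <- droplevels(data[ok, , drop = FALSE])
        cached <- list(data = sub,
                       base = if (length(unique(sub[[target_term]])) < 2)
                         NULL else ewas_base_fit(sub))
        base_cache[[key]] <- cached
      }
      if (is.null(cached$base)) {
        flag[i] <- "singular_design"
        next
      }
      f <- fit_probe_mixed_model(beta[i, ok], cached$data, target_term,
                                 engine, base = cached$base)
    }
    slope[i] <- f$slope; se[i] <- f$se; p[i] <- f$p
    method[i] <- f$method; flag[i] <- f$flag
  }
  dose0 <- sheet$dose == 0
  base_cols <- if (any(dose0)) dose0 else rep(TRUE, nrow(sheet))
  baseline <- rowMeans(beta[, base_cols, drop = FALSE], na.rm = TRUE)
  holm_p <- holm_adjust(p)
  fdr_q <- fdr_adjust(p)
  tier <- ifelse(is.na(p), "none",
                 ifelse(holm_p < nominal_alpha, "nominal",
                        ifelse(p < moderate_alpha, "moderate", "none")))
  out <- data.frame(
    probe_id = rownames(beta) %||% sprintf("p%06d", seq_len(n_probe)),
    slope = slope, se = se, p = p, holm_p = holm_p, fdr_q = fdr_q,
    direction = ifelse(is.na(slope), NA_character_,
                       ifelse(slope > 0, "hyper", "hypo")),
    baseline_beta = as.numeric(baseline),
    tier = tier, n_used = n_used, method = method, flag = flag,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "target_term") <- target_term
  class(out) <- c("association_table", "data.frame")
  out
}

#' Holm step-down adjusted p-values
#'
#' Step-down Bonferroni: sort ascending, multiply the i-th smallest of m
#' p-values by (m - i + 1), enforce a running maximum, cap at 1. Missing
#' entries are excluded from m and stay missing.
#'
#' @param p numeric p-values in `[0, 1]` (NA allowed).
#' @return adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) {
  adjust_ok(p, "holm")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment; monotone and capped at 1.
#' Missing entries are excluded from m and stay missing.
#'
#' @inheritParams holm_adjust
#' @return q-values in the original order.
#' @export
fdr_adjust <- function(p) {
  adjust_ok(p, "BH")
}

adjust_ok <- function(p, method) {
  if (!is.numeric(p)) stop_bad_arg("p", "must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop_bad_arg("p", "values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = method)
  out
}

#' Partition significant probes into dose-only, time-only and both
#'
#' Compares the dose- and time-association tables over an identical probe
#' universe and partitions the significant probes: sites associated with
#' dose but not time (the radiation-specific set), with time but not dose
#' (culture drift), and with both.
#'
#' @param dose_table,time_table [run_ewas()] tables over identical probes.
#' @param measure column to threshold (`"p"` for the moderate tier,
#'   `"holm_p"` for the nominal tier).
#' @param threshold significance cutoff applied to `measure` (strict `<`).
#' @return list of character vectors `dose_only`, `time_only`, `both`.
#' @export
classify_dose_time_sites <- function(dose_table, time_table,
                                     measure = c("p", "holm_p"),
                                     threshold = 0.001) {
  measure <- match.arg(measure)
  if (!setequal(dose_table$probe_id, time_table$probe_id))
    stop("dose and time tables cover different probe universes",
         call. = FALSE)
  sig <- function(tab) tab$probe_id[!is.na(tab[[measure]]) &
                                      tab[[measure]] < threshold]
  d <- sig(dose_table); t <- sig(time_table)
  list(dose_only = setdiff(d, t), time_only = setdiff(t, d),
       both = intersect(d, t))
}

#' Global dose trend on per-sample mean methylation
#'
#' Ordinary least squares of per-sample mean beta on dose, with time,
#' chip (batch) and row (array position) covariates; two-sided t-test on
#' the dose coefficient.
#'
#' @param sample_means named per-sample mean beta, as from
#'   [mean_sample_methylation()].
#' @param sheet sample sheet aligned with `sample_means`.
#' @return list with `slope` (beta per Gy), `se`, `p_value`, `n`.
#' @export
global_trend_test <- function(sample_means, sheet) {
  if (length(sample_means) != nrow(sheet))
    stop("sample_means and sheet differ in length", call. = FALSE)
  if (!is.null(names(sample_means)) && !is.null(sheet$sample_id))
    sample_means <- sample_means[sheet$sample_id]
  if (length(sample_means) < 3)
    stop("need at least 3 samples", call. = FALSE)
  if (length(unique(sheet$dose)) < 2)
    stop("need at least 2 dose levels", call. = FALSE)
  d <- data.frame(mb = as.numeric(sample_means), dose = sheet$dose,
                  time = sheet$time, chip = factor(sheet$chip),
                  row = factor(sheet$row))
  terms <- c("dose",
             if (length(unique(d$time)) > 1) "time",
             if (nlevels(d$chip) > 1) "chip",
             if (nlevels(d$row) > 1) "row")
  fit <- stats::lm(stats::reformulate(terms, response = "mb"), data = d)
  co <- summary(fit)$coefficients
  if (!"dose" %in% rownames(co) || is.na(stats::coef(fit)["dose"]))
    stop("dose coefficient is aliased (collinear design)", call. = FALSE)
  list(slope = co["dose", 1], se = co["dose", 2],
       p_value = co["dose", 4], n = nrow(d))
}

#' Per-time-point persistence of methylation changes
#'
#' For each probe, methylation change is expressed relative to that
#' probe's mean beta in the unexposed cultures at the earliest time point
#' (the reference group). The change is then summarized per dose-by-time
#' cell as quartiles over probes and replicates, showing whether induced
#' changes persist, decay or grow over time in culture.
#'
#' @param beta beta matrix.
#' @param sheet sample sheet; must contain 0-dose samples at the earliest
#'   time point.
#' @param probes probe ids to summarize (default all).
#' @return data.frame with `dose`, `time`, `n`, `q1`, `median`, `q3` of
#'   the per-observation delta beta.
#' @export
persistence_summary <- function(beta, sheet, probes = rownames(beta)) {
  if (!is.null(colnames(beta)) && !is.null(sheet$sample_id))
    beta <- beta[, sheet$sample_id, drop = FALSE]
  t0 <- min(sheet$time)
  ref <- sheet$dose == 0 & sheet$time == t0
  if (!any(ref))
    stop("no unexposed samples at the earliest time point", call. = FALSE)
  sub <- beta[probes, , drop = FALSE]
  ref_mean <- rowMeans(sub[, ref, drop = FALSE], na.rm = TRUE)
  delta <- sub - ref_mean
  cells <- unique(sheet[, c("dose", "time")])
  cells <- cells[order(cells$dose, cells$time), ]
  out <- lapply(seq_len(nrow(cells)), function(k) {
    cols <- sheet$dose == cells$dose[k] & sheet$time == cells$time[k]
    v <- as.vector(delta[, cols, drop = FALSE])
    v <- v[!is.na(v)]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(dose = cells$dose[k], time = cells$time[k], n = length(v),
               q1 = q[1], median = q[2], q3 = q[3])
  })
  do.call(rbind, out)
}
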