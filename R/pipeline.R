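#' Pipeline configuration
#'
#' Bundles the per-stage parameter blocks and stage toggles for
#' [run_pipeline()]. Any stage can be switched off; later stages check
#' that the artifacts they need were produced.
#'
#' @param sim a [sim_config()] block (the seed inside it drives every
#'   random stage).
#' @param qc a [qc_thresholds()] block.
#' @param ewas list with `nominal_alpha` (Holm threshold, default 0.05),
#'   `moderate_alpha` (uncorrected threshold, default 0.001),
#'   `classify_threshold` (dose/time partition cutoff on uncorrected p).
#' @param annotation list with `shore_width` (default 2000),
#'   `profile_flank` (2500), `bin_width` (20), `merge_map`.
#' @param signature list with `n_probes`, `n_pairs`, `signature_size`,
#'   `delta`, `noise_sd`, `n_resamples` (default 1000), `k` (2),
#'   `detection_alpha` (0.05).
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "preprocess", "ewas", "classify", "annotate",
#'   "signature")`.
#' @param outdir output directory, or `NULL` to skip writing artifacts.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(seed = 1),
                            qc = qc_thresholds(),
                            ewas = list(),
                            annotation = list(),
                            signature = list(),
                            stages = c("simulate", "preprocess", "ewas",
                                       "classify", "annotate", "signature"),
                            outdir = NULL) {
  stopifnot(inherits(sim, "sim_config"), inherits(qc, "qc_thresholds"))
  known <- c("simulate", "preprocess", "ewas", "classify", "annotate",
             "signature")
  if (!all(stages %in% known))
    stop_bad_arg("stages", paste("must be among:",
                                 paste(known, collapse = ", ")))
  ewas <- utils::modifyList(
    list(nominal_alpha = 0.05, moderate_alpha = 0.001,
         classify_threshold = 0.001), ewas)
  annotation <- utils::modifyList(
    list(shore_width = 2000, profile_flank = 2500, bin_width = 20,
         merge_map = default_state_merge()), annotation)
  signature <- utils::modifyList(
    list(n_probes = 20000, n_pairs = 18, signature_size = 800,
         delta = 0.3, noise_sd = 0.02, n_resamples = 1000, k = 2,
         detection_alpha = 0.05), signature)
  structure(list(sim = sim, qc = qc, ewas = ewas,
                 annotation = annotation, signature = signature,
                 stages = stages, outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON or YAML document
#'
#' Top-level blocks mirror the [pipeline_config()] arguments; the `sim`
#' block is passed to [sim_config()] (its `seed` is mandatory) and the
#' `qc` block to [qc_thresholds()].
#'
#' @param path config document path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  if (!is.null(raw$sim)) args$sim <- do.call(sim_config, raw$sim)
  if (!is.null(raw$qc)) args$qc <- do.call(qc_thresholds, raw$qc)
  for (nm in c("ewas", "annotation", "signature", "stages", "outdir"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  do.call(pipeline_config, args)
}

#' Run the analysis pipeline end to end
#'
#' Executes, in order: simulate (sample sheet, genome annotation, probe
#' manifest, intensities; plus the tumor/normal matrix for the signature
#' stage), preprocess (normalization, beta, QC), ewas on dose and on
#' time, classification of dose/time sites, genomic and chromatin
#' annotation with compartment enrichment of the dose-affected set, and
#' the Monte-Carlo signature test. Disabled stages are skipped; stages
#' whose inputs are missing raise an error naming the missing artifact.
#' All randomness derives from the seed in the `sim` block, so rerunning
#' an identical config reproduces every output byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return a run report (list) with per-stage row counts, exclusions and
#'   key results; written to `<outdir>/run_report.json` when `outdir` is
#'   set, along with per-stage TSV/BED/JSON artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  art <- function(...) file.path(outdir, paste0(...))
  state <- list()
  report <- list(seed = config$sim$seed, stages = st,
                 version = as.character(utils::packageVersion("methdose")))

  need <- function(what, stage) {
    if (is.null(state[[what]]))
      stop("stage '", stage, "' needs artifact '", what,
           "' (enable the stage that produces it)", call. = FALSE)
    state[[what]]
  }

  if ("simulate" %in% st) {
    sim <- config$sim
    state$sheet <- generate_sample_sheet(sim)
    gen <- generate_probe_annotation(sim)
    state$probes <- gen$probes
    state$annotation <- gen$annotation
    state$intensities <- generate_intensities(sim, state$sheet,
                                              state$probes)
    report$simulate <- list(n_samples = nrow(state$sheet),
                            n_probes = nrow(state$probes),
                            n_dose_probes = sum(state$probes$is_dose),
                            n_drift_probes = sum(state$probes$is_drift))
    if (!is.null(outdir)) {
      write_sample_sheet(state$sheet, art("sample_sheet.tsv"))
      write_intensities(state$intensities, art("intensities"))
      write_bed(state$annotation$cgi, art("cgi.bed"))
      write_bed(data.frame(chrom = state$annotation$genes$chrom,
                           start = pmin(state$annotation$genes$tss,
                                        state$annotation$genes$tes),
                           end = pmax(state$annotation$genes$tss,
                                      state$annotation$genes$tes),
                           name = state$annotation$genes$gene_id,
                           strand = state$annotation$genes$strand),
                art("genes.bed"))
      write_bed(state$annotation$chromatin, art("chromatin.bed"))
    }
  }

  if ("preprocess" %in% st) {
    x <- need("intensities", "preprocess")
    pp <- preprocess_pipeline(x, config$qc)
    state$beta <- pp$beta
    report$preprocess <- pp$n
    if (!is.null(outdir)) {
      write_matrix_tsv(pp$beta, art("beta.tsv"))
      jsonlite::write_json(
        list(removed_probes = pp$removed_probes,
             sample_report = pp$sample_report, n = pp$n),
        art("qc_report.json"), auto_unbox = TRUE, digits = NA,
        dataframe = "rows")
    }
  }

  if ("ewas" %in% st) {
    beta <- need("beta", "ewas")
    sheet <- need("sheet", "ewas")
    ew <- config$ewas
    state$dose_table <- run_ewas(beta, sheet, "dose",
                                 nominal_alpha = ew$nominal_alpha,
                                 moderate_alpha = ew$moderate_alpha)
    state$time_table <- run_ewas(beta, sheet, "time",
                                 nominal_alpha = ew$nominal_alpha,
                                 moderate_alpha = ew$moderate_alpha)
    trend <- global_trend_test(mean_sample_methylation(beta), sheet)
    report$ewas <- list(
      n_probes = nrow(state$dose_table),
      dose_moderate = sum(state$dose_table$tier != "none", na.rm = TRUE),
      time_moderate = sum(state$time_table$tier != "none", na.rm = TRUE),
      global_trend = trend)
    if (!is.null(outdir)) {
      write_association_table(state$dose_table, art("ewas_dose.tsv"))
      write_association_table(state$time_table, art("ewas_time.tsv"))
    }
  }

  if ("classify" %in% st) {
    dt <- need("dose_table", "classify")
    tt <- need("time_table", "classify")
    cls <- classify_dose_time_sites(dt, tt,
                                    threshold =
                                      config$ewas$classify_threshold)
    state$classes <- cls
    report$classify <- lapply(cls, length)
    if (!is.null(outdir))
      jsonlite::write_json(cls, art("site_classes.json"))
  }

  if ("annotate" %in% st) {
    probes <- need("probes", "annotate")
    ann <- need("annotation", "annotate")
    dt <- need("dose_table", "annotate")
    acfg <- config$annotation
    per_probe <- data.frame(
      probe_id = probes$probe_id,
      cgi_category = assign_cgi_category(probes, ann,
                                         shore_width = acfg$shore_width),
      tss_distance = signed_tss_distance(probes, ann$genes),
      chromatin_state = assign_chromatin_state(probes, ann,
                                               merge_map = acfg$merge_map),
      stringsAsFactors = FALSE)
    affected <- dt$probe_id[!is.na(dt$p) &
                              dt$p < config$ewas$moderate_alpha]
    state$probe_annotation <- per_probe
    if (length(affected)) {
      states <- stats::setNames(per_probe$chromatin_state,
                                per_probe$probe_id)
      state$enrichment <- compartment_enrichment(affected,
                                                 per_probe$probe_id,
                                                 states)
    }
    report$annotate <- list(
      n_affected = length(affected),
      category_counts = as.list(table(per_probe$cgi_category)))
    if (!is.null(outdir)) {
      utils::write.table(per_probe, art("probe_annotation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(state$enrichment))
        utils::write.table(state$enrichment, art("enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("signature" %in% st) {
    scfg <- config$signature
    tn <- generate_tumor_normal(scfg$n_probes, scfg$n_pairs,
                                scfg$signature_size, scfg$delta,
                                scfg$noise_sd,
                                seed = config$sim$seed + 7L)
    pool <- setdiff(rownames(tn$beta), tn$signature_probes)
    res <- monte_carlo_signature_test(tn$beta, tn$labels,
                                      tn$signature_probes,
                                      pool_probes = pool,
                                      n_resamples = scfg$n_resamples,
                                      seed = config$sim$seed + 8L,
                                      k = scfg$k)
    state$signature <- res
    report$signature <- list(observed_p = res$observed_p,
                             mc_p = res$mc_p,
                             null_median = res$null_median)
    if (!is.null(outdir))
      write_signature_test(res, art("signature_test.json"),
                           null_tsv = art("signature_null_p.tsv"))
  }

  if (!is.null(outdir))
    jsonlite::write_json(report, art("run_report.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(c(report, list(state = state)))
}
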