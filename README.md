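# methdose

Dose-response DNA methylation analysis for radiation-exposed cell
cultures, with a seed-controlled simulator for every input.

## What it is for

Experiments that expose cultured cells (e.g. bronchial epithelium) to
graded doses of ionizing radiation and profile CpG methylation on a
450K-style array over weeks in culture pose four linked questions: which
CpGs respond to *dose*; which merely *drift* with time in culture; in what
genomic/chromatin context the dose-responsive sites sit; and whether those
sites, as a signature, discriminate tumor from normal tissue better than
random probe sets. `methdose` implements that full analysis path for
R users working with probe-level intensity tables:

- **Preprocessing** — joint quantile normalization of methylated (M) and
  unmethylated (U) signals, beta values `β = M/(M+U)`, detection-p
  masking, probe- and sample-level QC with an auditable exclusion report.
- **Per-CpG mixed-model EWAS** — for each probe,
  `β ~ dose + time + row + (1 | chip)` fitted by REML, Wald t-tests on the
  dose (or time) coefficient, Holm and Benjamini–Hochberg corrections,
  direction and significance tiers, dose/time site classification,
  a global mean-β dose-trend test, and per-time-point persistence
  summaries.
- **Annotation** — CpG island / 5′-shore / 3′-shore / gene-body
  categories (strand-aware, 2 kb shores), signed nearest-TSS distances,
  island-scaled meta-coordinates, chromatin-state lookup with enhancer /
  transcription state merging, Fisher's-exact compartment enrichment with
  Woolf confidence intervals, and 20-bp tag-density profiles from read
  intervals.
- **Signature testing** — complete-linkage clustering of Manhattan
  distances cut at k = 2, chi-square cluster/label association, and a
  Monte-Carlo p-value against `M = 1000` random probe sets.
- **Simulation** — sample sheets, a synthetic genome (islands, genes,
  chromatin tiling), intensity matrices with planted dose effects
  (direction coupled to baseline methylation and chromatin context),
  methylation drift, chip/row batch effects, detection failures, paired
  tumor/normal β matrices with a planted discriminating signature, and
  enriched read intervals — all bit-reproducible from one seed.

## Worked example

Simulate a 48-sample heavy-ion series (4 doses × 4 time points × 3
replicates) with 200 dose-responsive probes planted at +0.05 β/Gy, run
QC and the dose EWAS, and test the signature in simulated tumor/normal
pairs:

```r
library(methdose)

cfg <- sim_config(n_probes = 4000, n_dose_probes = 200,
                  dose_effect = 0.05, seed = 1)
sheet  <- generate_sample_sheet(cfg)
layout <- generate_probe_annotation(cfg)
pp  <- preprocess_pipeline(generate_intensities(cfg, sheet, layout$probes))
tab <- run_ewas(pp$beta, sheet, target_term = "dose")
table(tab$tier)
#>
#> moderate  nominal     none
#>       40      165     3795

tn  <- generate_tumor_normal(20800, n_pairs = 18, signature_size = 800,
                             delta = 0.3, noise_sd = 0.02, seed = 2)
res <- monte_carlo_signature_test(
  tn$beta, tn$labels, tn$signature_probes,
  pool_probes = setdiff(rownames(tn$beta), tn$signature_probes),
  n_resamples = 1000, seed = 3)
res
#> <signature_test> observed chi-square p = 1.97e-09
#>   Monte-Carlo p = 0.000999 (M = 1000, seed 3)
#>   null p range 0.000407-1; median 0.4795
```

Reading the output: 197 of the 200 planted probes are recovered
(`nominal` = Holm-corrected p < 0.05, `moderate` = uncorrected p < 0.001
only), and the planted signature's clustering separates tumor from normal
perfectly (chi-square p ≈ 2e-9), which no random probe set matches —
the Monte-Carlo p sits at its 1/1001 floor.

An end-to-end run from a single config (stages: simulate → preprocess →
EWAS → classify → annotate → signature) is
`run_pipeline(pipeline_config(...))`, or from a shell:

```sh
Rscript inst/scripts/methdose-pipeline.R --config cfg.yaml --outdir out/
```

The methods vignette (`vignettes/methdose-methods.Rmd`) documents the
model, the QC rules, the annotation conventions, the Monte-Carlo
estimator's tie behavior, and every tunable default.

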