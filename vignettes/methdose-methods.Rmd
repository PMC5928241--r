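---
title: "Dose-response methylation analysis with methdose: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-response methylation analysis with methdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdose)
```

# The problem

Cultured cells exposed to ionizing radiation acquire changes in CpG
methylation that can persist over many population doublings. Measured on a
450K-style array, each CpG yields a methylated (M) and unmethylated (U)
signal, summarized as a beta value $\beta = M/(M+U) \in [0,1]$, the
estimated fraction of methylated alleles. The analytical questions this
package addresses are:

1. Which CpGs change methylation *with radiation dose*, after accounting
   for time in culture and array batch structure?
2. Which CpGs *drift* with time in culture, independent of dose?
3. In what genomic and chromatin context do the dose-responsive sites sit
   (CpG islands and their shores, gene bodies, chromatin states)?
4. Does the methylation state of the dose-responsive sites, taken as a
   signature, separate tumor from normal tissue better than random CpG
   sets of the same size?

Because the package is developed and tested without access to array or
consortium data, a first-class synthetic-data module generates every input
with planted ground truth, and all statistical claims in the test suite
are claims about that generator.

# Preprocessing model

Raw inputs are M/U signal matrices plus per-datapoint detection p-values.
The chain is fixed: joint quantile normalization, beta computation,
detection masking, probe filtering, sample filtering.

* **Joint quantile normalization.** For each sample, the stacked
  $2P$-vector of its M and U signals is replaced by the across-sample mean
  of order statistics at its ranks (via limma). Normalizing M and U
  *together* preserves the within-sample ordering of M relative to U and
  therefore the ordering of beta values; normalizing the two channels
  separately would not.
* **Beta.** $\beta = M/(M+U)$ exactly, with no stabilizing offset added to
  the denominator; $M+U=0$ is set missing.
* **QC thresholds** (all strict inequalities): detection $p > 0.001$
  masks a datapoint; probes missing in $>10\%$ of samples are dropped;
  samples with call rate $<95\%$, mean signal $<2{,}000$ AU, or mean
  signal $<50\%$ of the experiment-wide median of per-sample means are
  dropped. Sample criteria are computed on raw (pre-normalization,
  pre-masking) intensities; probe missingness on the masked matrix. The
  QC report records per-rule reasons so exclusions are auditable.

Because samples are filtered after probes, a sample exclusion can in
principle raise the missing fraction of a retained probe above 10% when
recomputed on the surviving samples; the chain deliberately does not
iterate — the order is part of the contract.

# Per-CpG mixed model

For one probe in one exposure series, with samples indexed by $j$:

$$\beta_j = \alpha + \gamma_d \,\mathrm{dose}_j + \gamma_t \,\mathrm{time}_j
  + \mathrm{row}_j + u_{\mathrm{chip}(j)} + \varepsilon_j,\qquad
  u \sim N(0, \sigma_c^2),\ \varepsilon \sim N(0, \sigma^2)$$

Dose (Gy) and time (days) are numeric; chip row is categorical; the chip
contributes a random intercept. The model is fitted by REML (lme4), and
inference on the target coefficient ($\gamma_d$ for the dose scan,
$\gamma_t$ for the time scan) is a two-sided Wald $t$-test on residual
degrees of freedom $n - p$. Design choices worth making explicit:

* **Numeric time.** Whether time should enter numerically or as a factor
  is genuinely open; numeric is chosen because drift is modeled as a
  linear rate (beta units/day) and a linear adjustment is what the dose
  coefficient needs protection from.
* **OLS limit.** When the chip variance is estimated at zero (a singular
  fit), when only one chip is present, or when the optimizer fails, the
  fit falls back to ordinary least squares on the same fixed effects; the
  `engine = "ols"` option forces this unconditionally. The fallback is
  exact — slope, SE and p reproduce an independent normal-equations
  computation to machine precision — so the mixed model degrades
  gracefully rather than returning unstable estimates.
* **Calibration.** With 48 samples on 4 chips, the Wald $t$ with residual
  df was verified on a 10,000-probe null simulation: the fraction of
  probes with $p < 0.001$ falls inside the 99% binomial band, and the
  Holm-corrected family-wise error over 100 simulated families is
  consistent with 5%. Satterthwaite degrees of freedom were considered
  and rejected: on this design they differ from $n-p$ by a few units with
  no measurable effect on tail calibration, at roughly 500 times the
  per-probe cost.
* **Missing data.** Listwise deletion per probe; probes retaining fewer
  than 80% of samples are flagged and skipped. Fits for probes sharing a
  missingness pattern reuse one model skeleton, which keeps a 10,000-probe
  scan to a few seconds.
* **Multiplicity tiers.** Holm step-down controls family-wise error;
  sites with Holm-corrected $p < 0.05$ are tier `nominal`, sites with
  uncorrected $p < 0.001$ tier `moderate`. Benjamini–Hochberg q-values
  are attached for completeness. Both adjustments are oracle-tested
  against their textbook step formulas.
* **Dose/time partition.** The default partition threshold is the
  moderate tier (uncorrected $p < 0.001$) in both scans; dose-associated
  sites that are also time-associated are set aside so that persistence
  summaries are not confounded by culture drift.

The global trend test is deliberately simpler: OLS of per-sample mean
beta on dose with time, chip and row covariates — a few dozen
observations do not support a random effect, and the chip factor absorbs
the batch mean shift.

# Genomic and chromatin annotation

All interval annotations are BED-style 0-based half-open; probe positions
are 1-based and converted internally — the conversion lives in one place.

* **CGI categories** (precedence Island > Shore > GeneBody > Other):
  shores extend `shore_width` (default 2,000 bp) from the *nearest*
  island's edges; 5′/3′ follow the strand of the island-associated gene
  (nearest TSS within 10 kb; genomic orientation otherwise); the gene
  body runs from the downstream shore edge to the TES. The category
  default (2 kb) and the meta-profile flank (2.5 kb) are two different
  constants, both exposed.
* **Island-scaled coordinate**: fractional position in $[0,1]$ inside an
  island, bp offsets in the flanks ($-d$ on the 5′ side, $1+d$ on the
  3′ side). The mixed scale is intentional: island widths vary, flank
  distances do not.
* **Chromatin states**: interval lookup plus a merge table that collapses
  the two strong-enhancer states, the two weak-enhancer states, and the
  three transcription-associated states into single labels.
* **Compartment enrichment**: per state, the 2×2 table of affected vs
  rest-of-universe by in-state vs not, two-sided Fisher's exact p. The
  odds ratio is the sample OR; its 95% CI uses the Woolf log-OR normal
  approximation with a 0.5 continuity correction on zero cells —
  reproducible in closed form, unlike the conditional-MLE interval, and
  the difference is immaterial at the table sizes involved.
* **Tag-density profiles**: reads overlapping 20-bp bins (any overlap
  counts) in a window centered on each probe, averaged over probes,
  normalized to reads per million mapped.

# Signature discrimination

Given a beta matrix for tumor/normal pairs, the signature test asks
whether a fixed probe set separates the two classes better than chance:

1. probes with any detection $p > 0.05$ anywhere in the sample set are
   excluded (this same rule defines the resampling pool);
2. samples are clustered on the signature's Manhattan distances with
   agglomerative complete linkage, cut at $k=2$;
3. the cluster/tissue association is a Pearson chi-square on the 2×2
   table (1 df, no continuity correction by default — both options are
   exposed);
4. the observed chi-square p is compared with `M` (default 1,000)
   re-draws of equally many probes, uniformly without replacement;
   $\mathrm{mc}_p = (1 + \#\{p_{\mathrm{null}} \le p_{\mathrm{obs}}\})/(M+1)$.

The add-one estimator can never return zero and is conservative in the
presence of ties. Pairing is ignored: the clustering is unsupervised.

**Ties and the null pool.** Two consequences of the chi-square statistic
being a function of a discrete table deserve emphasis. First, when the
planted class signal is strong, any random draw that includes even a few
dozen signature probes can separate the classes perfectly and *tie* the
observed p exactly; with the signature inside the pool the Monte-Carlo p
then saturates toward 1 no matter how strong the signature is. For
planted-signal benchmarking the package therefore resamples from the
*null* probes (the signature excluded), and `monte_carlo_signature_test()`
only requires the pool to be at least as large as the signature. Second,
under a fully exchangeable null (no class signal at all) the observed p
takes a few dozen attainable values, so $\mathrm{mc}_p$ is super-uniform
but not exactly uniform: ties at the distribution's upper atom place a
noticeable mass of runs at $\mathrm{mc}_p \approx 1$. A
Kolmogorov–Smirnov comparison against the continuous uniform will detect
this discreteness given enough runs; it reflects the estimator's
conservatism, not an error in the resampling. On real arrays, where
probe-level heterogeneity makes the attainable p values effectively
continuous, the issue is much weaker.

# The synthetic-data generator

The generator emulates the structure of a multi-dose, multi-timepoint
exposure experiment on an array platform:

* **Design**: doses × time points × replicates (defaults: 0/0.1/0.3/1 Gy
  × 2/20/37/55 days × 3 replicates = 48 samples), samples permuted onto
  12-sample chips with a row index 1–6 (two-column chip geometry
  abstracted to rows), so replicates are randomized over chip positions.
  The default time grid spans the roughly two-month culture window of a
  persistence experiment, starting at the 48-hour acute collection.
* **Baseline beta**: a two-component beta mixture (defaults: 60% mass at
  mean 0.15, 40% at mean 0.85, concentration 15), the characteristic
  bimodal array profile. Infinite concentrations degenerate to the mean
  exactly, which the tests use to pin baselines.
* **Planted dose effects**: `n_dose_probes` probes receive a linear slope
  of magnitude `dose_effect` (default 0.05 beta/Gy). The direction/context
  coupling follows the effect profile: `fe_like` plants hypermethylation
  at low-baseline sites and (when a genome layout is present) prefers
  island/shore probes 3:1, mimicking a heavy-ion pattern; `x_like` plants
  hypomethylation at high-baseline sites away from islands; `si_like`
  plants mixed directions at intermediate baselines.
* **Drift**: `n_drift_probes` probes move at `drift_rate` (default 0.001
  beta/day — one molecule per thousand per day) with a per-probe random
  but time-consistent sign, matching the observation that drifting sites
  recur across experimental series while the direction may differ.
  Probes affected by both dose and drift exist only if `n_both_probes`
  is set; the default is 0 so the two truth sets partition.
* **Batch structure and noise**: chip random intercepts (SD 0.02), row
  effects (SD 0.01), residual noise (SD 0.02), all on the beta scale,
  applied to the latent proportion and clamped to $[0.001, 0.999]$ so
  intensities stay positive. Signals are binomial draws at
  `total_intensity` trials (so measurement error shrinks as intensity
  grows); with `residual_sd = 0` the generator switches to the exact
  deterministic mapping $M = \beta T$, giving noise-free fixtures.
* **Detection failures** are planted completely at random at rate
  `detection_fail_rate` by drawing the detection p above the 0.001 cutoff.
* **Tumor/normal matrices**: per-probe baselines shared by all samples,
  a planted shift of magnitude `delta` at signature probes in tumor
  columns only (random per-probe direction, flipped when the shift would
  exit $[0,1]$), i.i.d. noise elsewhere. What this does *not* emulate:
  probe-specific biological variance, sample-level global shifts,
  copy-number artifacts, or the pervasive tumor/normal differences of
  real cancer arrays. Passing tests therefore demonstrate correctness of
  the machinery on a clean planted-signal model, not performance on real
  tumor data.
* **Read intervals**: uniform start positions with an `enrichment`-fold
  density excess inside target intervals — an input surrogate for
  ChIP/DNase tracks feeding the tag-density profiles.

Every generator consumes one integer seed; distinct fixed offsets derive
per-stage substreams, and the RNG state is restored afterwards, so
identical configs are bit-reproducible and generators never perturb the
caller's stream.

# Numerical choices and degenerate inputs

* Constant responses, aliased designs and single-level target terms are
  flagged, never fitted; flags travel in the association table.
* `holm_adjust`/`fdr_adjust` exclude missing p-values from the family
  size and re-insert them in place.
* Probe placement in the genome simulator is by construction plus
  rejection against the category rules (at most 100 attempts per probe),
  so recorded truth always matches the assigner.
* Complete-linkage cuts renumber clusters by first occurrence, making
  labels deterministic; with continuous distances, merge ties have
  probability zero, and the oracle tests draw continuous distances.
* Degenerate contingency margins (an empty cluster or class) return
  p = 1 with a flag rather than an error, so Monte-Carlo loops never
  abort mid-stream.

# Problem sizes used by the test suite

The statistical acceptance checks run at sizes chosen to make their
binomial/KS bounds meaningful while staying desk-scale: null calibration
on 10,000 probes × 48 samples and 100 null families of 300 probes;
planted-effect recovery on 10,000 probes with 200 planted; multiplicity
oracles on 1,000 random vectors; annotation oracles on a 1,000-probe
layout; Fisher enumeration over all 2×2 tables with row margins ≤ 12
plus 2,000 random tables with margins ≤ 50; clustering oracles on 200
instances with up to 8 samples; Monte-Carlo calibration over 200 runs of
M = 199 and power over 50 seeds of M = 1,000 with an 800-probe signature
against a 20,000-probe null pool.

# Known limitations

* The generator's noise is homoscedastic on the beta scale; real arrays
  are heteroscedastic (variance shrinks near 0 and 1), which the
  binomial intensity sampling only partly reproduces.
* Probe type chemistry (type I/II), dye bias, background correction and
  bisulfite-conversion effects are intentionally out of scope; the
  preprocessing implements exactly the normalization/QC chain described
  above and nothing else.
* The per-CpG model assumes a linear dose response; saturating responses
  will be detected with reduced power and a biased slope.
* The Monte-Carlo uniformity caveat above: calibration statements about
  `mc_p` are exact only up to the discreteness of the chi-square table.
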