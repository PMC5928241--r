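Package: methdose
Title: Dose-Response DNA Methylation Analysis for Radiation-Exposed Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for array-based dose-response DNA methylation
    studies of irradiated cell cultures. Converts methylated/unmethylated
    probe intensities to quality-controlled beta-value matrices, fits a
    per-CpG linear mixed model of methylation on radiation dose (or
    time-in-culture) with chip random effects, applies Holm and
    Benjamini-Hochberg multiplicity corrections, classifies dose-, drift-,
    and jointly-associated sites, annotates probes to CpG island, gene and
    chromatin-state context with Fisher's exact compartment enrichment and
    tag-density profiles, and evaluates methylation signatures by
    complete-linkage clustering of tumor/normal beta matrices with a
    Monte-Carlo resampling null. A seed-controlled synthetic-data generator
    produces every input the pipeline consumes, including planted dose
    effects, methylation drift, chip/row batch structure and detection
    failures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    limma,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
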