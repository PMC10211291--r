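Package: methylcell
Title: Cell-Type-Resolved Smoking Methylation Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for cell-type-resolved epigenome-wide
    association analysis of smoking: reference-based leukocyte
    deconvolution by constrained projection, per-cell-type robust-regression
    EWAS on M-values with multiple-testing and cell-type-specificity calls,
    proportion-weighted composite reconstruction of whole-blood effects,
    naive-to-memory B cell subtype-shift testing, integration of
    smoking-associated CpGs with mQTL, LD, GWAS, eQTM and eQTL evidence, and
    enrichment against curated EWAS catalog CpG sets. Includes a synthetic
    cohort generator with known ground truth so every stage is testable
    without external data, plus readers and writers for the plain-text
    formats the pipeline consumes and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    quadprog,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
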