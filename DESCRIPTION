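Package: mpnstdetect
Title: Detecting Malignant Transformation in NF1 Nerve Sheath Tumors from
    Single-Cell Transcriptomes and Plasma Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying malignant transformation of NF1-associated
    peripheral nerve sheath tumors. Implements single-cell quality control,
    normalization and variable-gene selection; cluster composition analysis
    with a Pearson-residual enrichment score against the plexiform
    neurofibroma baseline; reference-based cell-type label transfer with a
    per-cell prediction confidence; expression-based copy-number inference
    along genomic coordinates with discrete state calling and a per-cell
    aneuploidy (cnv) score; a per-cell malignant score combining label,
    confidence and aneuploidy; and a plasma proximity-extension-assay
    workflow (limit-of-detection imputation, ANOVA with Tukey HSD,
    scRNA-seq-informed biomarker panel selection, and a repeated
    cross-validated SVM "MPNST probability score"). A seeded synthetic-data
    module generates cell atlases and plasma cohorts with planted ground
    truth so the whole chain is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
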