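Package: mitoprostat
Title: Calcium Calibration, Co-Regulation and Translatome Analysis for
    Mitochondrial Proteostasis Studies
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for studies of impaired mitochondrial calcium
    homeostasis and the proteostatic response it evokes. Converts aequorin
    luminescence traces into calibrated free-calcium concentrations and
    extracts transient response signatures (peak amplitude, curve area, peak
    time); merges transcript and protein fold-change tables and classifies
    gene products into the four co-regulation quadrants (co-up,
    post-transcriptionally increased, co-down, post-transcriptionally
    repressed) with hypergeometric set enrichment; computes per-gene
    translational efficiency from monosome and polysome RNA-seq count
    matrices, fits partial least-squares discriminant analysis (PLS-DA)
    models, and selects significantly altered translational-efficiency genes
    by fold-change and Variable Importance in Projection (VIP) score.
    Includes synthetic-data generators with known ground truth for every
    stage and a reproducible pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    mixOmics,
    pracma
Config/testthat/edition: 3
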