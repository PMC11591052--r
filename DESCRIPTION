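Package: ecdymet
Title: Transcript-Length Bias Correction and Energy-Metabolism Statistics
    for Ecdysteroid Cell-Culture Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable implementation of the computational analyses used in
    cell-culture studies of 20-hydroxyecdysone (ecdysterone): a minimal
    negative-binomial differential-expression engine (median-of-ratios
    normalization, method-of-moments dispersion, conditional exact test,
    Benjamini-Hochberg adjustment), a transcript-length fold-change bias
    correction that regresses log2 fold change on log2 transcript length,
    subtracts the fitted line and reconciles initial and corrected estimates
    by a minimum-absolute-value / sign-flip rule, a Seahorse extracellular-flux
    ATP-rate decomposition into mitochondrial and glycolytic production rates,
    and the supporting bench-assay statistics (2^-ddCt relative quantification,
    densitometry normalization, percent-of-control, exact Mann-Whitney and
    pooled-variance t tests). Seeded synthetic-data generators with the same
    statistical structure make the whole pipeline testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
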