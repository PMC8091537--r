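Package: tlv
Title: Trendline Variability Screening for RNA-Seq Count Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Intra-group variability screen for RNA-seq count matrices.
    Implements Minimum Value Adjustment (MVA) scaling, rank-order
    "trendline" statistics (coefficient of variation, range ratios,
    skewness, kurtosis, quartile-segment slope ratios, R-squared of the
    rank-ordered profile) that detect tailed or divergent gene
    expression, correlation-based gene-module discovery with calibrated
    thresholds, per-individual positional-rank scoring, and a local
    hypergeometric over-representation test against user-supplied gene
    sets. Includes a synthetic count-matrix generator with ground-truth
    labels, a one-command pipeline, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    DESeq2,
    optparse,
    withr
Config/testthat/edition: 3
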