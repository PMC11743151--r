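Package: miractivity
Title: MicroRNA Activity Inference from Single-Cell and Spatial
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Infers per-cell and per-spot microRNA activity from raw count
    matrices by testing whether each microRNA's experimentally supported
    target genes concentrate at the low end of the z-score-ranked
    expression profile of every cell or spot, using the exact
    minimum-hypergeometric (mHG) test with a path-counting p-value.
    Activity p-values are aggregated into spatial, total, and comparative
    activity reports with Wilcoxon rank-sum differential testing and
    Benjamini-Hochberg false-discovery control.  Includes filtering and
    indexing of miRNA-target interaction catalogues, readers for dense and
    MatrixMarket count formats, synthetic data generators with planted
    activity for calibration studies, and ggplot2-based activity maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    parallel,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    uwot
Config/testthat/edition: 3
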