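Package: matriscope
Title: Matrisome-Centric Proteomic Profiling of Decellularized Tumor Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for extracellular-matrix (ECM) centric
    analysis of multi-plex TMT proteomics from decellularized tissue:
    two-stage reference-channel normalization across TMT plexes, matrisome
    annotation and relative percent composition profiling, differential
    matrisome protein calling by Welch's t-test with fold-change
    thresholding, cellular-origin assignment of proteins from single-cell
    expression, single-sample rank-based gene-set (ssGSEA) scoring of cells
    and bulk cohorts, and Kaplan-Meier / log-rank survival stratification.
    Ships a synthetic-data generator that emulates a multi-plex tumor/normal
    cohort design with planted effects, so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    mclust,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
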