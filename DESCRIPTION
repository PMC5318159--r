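Package: ribostruct
Title: mRNA Structure and Translation Efficiency from DMS-Seq and Ribosome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide analysis of bacterial mRNA secondary structure and its
    relationship to translation. Converts per-base DMS-seq count tracks into
    normalized reactivities and unpaired-base calls, quantifies ORF-wide
    structure with Lorenz-curve Gini indices, computes corrected ribosome
    footprint densities and translation efficiencies, identifies adjacent ORF
    pairs residing on the same polycistronic message, predicts
    constraint-guided RNA secondary structures with an exact base-pair-counting
    engine (minimum free energy and McCaskill-style pair probabilities),
    measures folding directionality across ORF boundaries, computes tRNA
    adaptation indices, and provides the supporting correlation, bootstrap,
    ROC, stepwise-regression and outlier statistics. A synthetic-data module
    generates annotation, ground-truth structures and sequencing tracks so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
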