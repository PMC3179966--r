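Package: wssdr
Title: Segmental Duplication Detection from Whole-Genome Shotgun Read Depth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects large (>= 10 kb), high-identity (> 94%) segmental
    duplications in an assembled genome from the depth of whole-genome
    shotgun reads aligned back to the assembly (the WSSD strategy).
    Implements repeat-masking settings with distinct mask and assembly-gap
    tracks, windows of exactly one thousand unmasked bases (kub) with
    sliding 5-kub aggregation, read QC and alignment filtering with
    match-midpoint depth counting, a constrained four-Gaussian maximum
    likelihood calibration of depth thresholds from single-copy regions,
    duplication calling by the six-of-seven consecutive-window rule, and
    downstream summaries: per-chromosome duplication tables, gene content
    and density, protein-domain enrichment, and nuclear organelle DNA
    (NUMT/NUPT) quantification. A seeded synthetic-data generator produces
    genomes with implanted duplications, divergent repeat families, gaps,
    organelle insertions and shotgun reads, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    Rcpp,
    methods,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
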