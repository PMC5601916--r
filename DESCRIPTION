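Package: corepressmap
Title: Multi-Omic Mapping of a Corepressor Module from ChIP-MS, Cistrome
    and Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores an in vivo cross-linked ChIP-MS interactome from peptide
    intensities (iBAQ quantification, median normalization, downshifted-Gaussian
    imputation, homoscedastic t-tests and fold/P interactor gates), classifies
    interactions by nuclease sensitivity, intersects transcription-factor
    cistromes with reciprocal-overlap co-binding and knockout-dependency
    calling, compares position-weight-matrix motif enrichment between peak
    classes, links peaks to genes under nearest-gene and promoter-window
    conventions, and tests the association between dependent co-bound sites
    and coregulated genes. A seeded synthetic-data generator emulates the
    statistical structure of such a study (spiked interactors with
    intensity-dependent missingness, motif-nucleated co-bound peaks that
    collapse in a knockout, and coupled expression changes) so the whole
    inference chain is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
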