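Package: crosscortex
Title: Cross-Species Comparison of Cortical Cell-Type Organization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable pipeline for comparing cortical
    cell-type organization between species from single-nucleus and spatial
    transcriptomics plus immunofluorescence histology. Provides reference
    annotation repair (3' UTR extension and intergenic read profiling),
    single-nucleus QC, normalization, embedding and clustering, balanced
    cross-species label transfer, principal convex hull (archetypal) analysis
    of intratelencephalic neuron continua with automated vertex-count
    selection, laminar spatial statistics for cortical pseudocolumns (subpial
    density profiles, Gini confinement, depth-axis partial correlations), and
    perineuronal-net enrichment metrics with depth-matched nulls. A synthetic
    data generator emulates the statistical structure of all input modalities
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Matrix,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    readr,
    jsonlite,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    EBImage,
    tiff,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
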