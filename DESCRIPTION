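Package: gutmosaic
Title: Spatial Structure and Time-Series Interaction Analysis of Gut Microbiota
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for joint spatial and temporal analysis of gastrointestinal
    microbiota from 16S rRNA OTU count tables. Implements library-size
    normalization by common scaling, prevalence and consistency filtering,
    alpha diversity and Bray-Curtis/NMDS/ANOSIM ordination, classification of
    per-OTU abundance profiles along the GI tract into six spatial categories
    (monotonic gradients, broken-stick gradients with breakpoints, habitat
    specialists and avoiders), pairwise discrete-time interaction inference
    from daily fecal time series with permutation robustness testing,
    Spearman and SparCC co-occurrence matrices in temporal and spatial
    flavors, and the concordance analyses linking temporal interactions to
    spatial co-occurrence. Includes a ground-truthed synthetic data generator
    so the full pipeline is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    vegan,
    edgeR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    biomformat,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
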