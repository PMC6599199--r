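Package: polysweep
Title: Selective Sweep Scans and Expression Diversification in Allopolyploid Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting selective sweeps and expression
    diversification between genetic clusters of an allopolyploid crop from
    transcriptome-derived SNPs. Implements a SNP filter cascade with
    sub-genome partitioning, windowed nucleotide diversity and
    Weir-Cockerham FST, linkage-disequilibrium decay curves, a
    cross-population composite-likelihood sweep scan (XP-CLR style) with a
    pi-ratio track and percentile-based candidate-region calling,
    differential-expression thresholding with sub-genome asymmetry tests,
    and metabolic-network expression overlays. A seeded synthetic-data
    generator produces genotype, map, annotation, expression and network
    inputs with the statistical structure the analysis assumes, so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
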