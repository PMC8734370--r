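Package: circaloop
Title: Diurnal RNAPII Chromatin Interactions and Rhythmic Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking rhythmic RNA polymerase II occupancy to
    diurnal chromatin interactions. Provides cosinor-based rhythm and phase
    detection on diurnal time courses with Benjamini-Hochberg correction,
    peak-to-gene assignment and RG/NG/NEG gene classification, ChIA-PET loop
    filtering and gene-pair coexpression/phase statistics with distance-matched
    random controls, chromatin spatial cluster (CSC) construction and AM/PM/static
    classification with permutation-based phase-enrichment tests, clock-gene-seeded
    connectivity networks, binned contact matrices with iterative correction, and
    TSS-centered aggregate interaction profiles. Includes a seeded synthetic-data
    generator emulating the statistical structure of a diurnal ChIA-PET study so
    every stage is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    igraph,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
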