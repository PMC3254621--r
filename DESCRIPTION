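Package: qtlspan
Title: Two-QTL Epistasis Scans and Cross-Locus Protein Network
    Prioritization for F2 Intercrosses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for mapping pairs of interacting quantitative trait
    loci (QTLs) in F2 intercross data and linking them to candidate
    interacting gene networks.  Provides simulation of F2 genotypes under
    a Haldane meiosis model with epistatic phenotypes, single-QTL and
    two-dimensional two-QTL marker-regression genome scans with
    genome-wide permutation thresholds, delimitation of non-recombinant
    haplotype windows around interacting loci with interval-to-gene-list
    mapping, and prioritization of cross-locus protein-protein
    interactions by degree-preserving network randomization (SPAN) with
    node- and edge-level false discovery rate control.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    withr,
    igraph,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
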