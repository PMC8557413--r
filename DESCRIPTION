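Package: srnacons
Title: Conservation and Promoter-Region Analysis of Antisense Small RNAs
    in Reduced Endosymbiont Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of antisense small RNAs
    (asRNAs) in gene-dense, AT-rich bacterial endosymbiont genomes.
    Classifies predicted small-RNA transcripts against a genome
    annotation, calls orthologous asRNAs between two lineages through a
    whole-genome-alignment offset map with a coordinate-proximity rule,
    tests whether the protein region encoding a conserved asRNA is more
    conserved than the surrounding protein with a sliding-window
    maximum-likelihood amino-acid divergence test, counts compensatory
    basepair changes in consensus secondary structures, and analyses
    61-nt upstream regions with 7-nt sliding windows for GC content
    (against a sequence-reshuffle permutation null), GC skew, and IUPAC
    motif occurrences.  A seeded synthetic-data generator produces
    paired symbiont-like genomes with planted signals so that every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    utils,
    withr
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
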