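Package: crisprkit
Title: CRISPR Knockout Consequence Analysis and Gene-Family Population Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing CRISPR/Cas9 knockout experiments in plant
    genes, built around the rice auxin repressor gene family (Aux/IAA).
    Provides gene-family population-genetics statistics (Jukes-Cantor
    corrected nucleotide diversity, Nei-Gojobori Ka/Ks, Tajima's D, Kimura
    2-parameter distances and neighbor-joining trees), inference and
    protein-consequence classification of CRISPR-induced edits, splice
    junction quantification from spliced alignments with reading-frame
    restoration ("rescue") prediction and mosaic transcript construction,
    a genome-wide off-target variant screen with an effective-mutation
    filter, relative expression by the 2^-ddCt method, and seed-deterministic
    synthetic data generators (Hudson coalescent alignments, junction-
    spanning reads, variant tables) so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    rtracklayer,
    optparse,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    ape,
    jsonlite,
    phangorn,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
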