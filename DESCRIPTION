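Package: ctrkit
Title: Determining Complex Tandem Repeat Structure from Long Accurate Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for resolving the structure of complex tandem repeats
    (TRs) from long, accurate sequencing reads. Selects repeat units by a
    greedy parsimony penalty and decomposes a TR into unit copies with a
    dynamic program; clusters per-individual reads into one or two TR
    alleles and population alleles into TR representatives by
    neighbor-joining with a diameter-validity criterion; calls reliable
    flanking substitutions under an exact binomial sequencing-error model
    and groups representatives by their nearest flanking SNVs; merges
    detector outputs into a non-overlapping TR locus catalog and extracts
    per-read TR segments from anchoring alignments; summarises per-locus
    divergence (median length, IQR ratio, weighted mutation rate,
    complexity, extension); evaluates a Lander-Waterman read-coverage
    detection model; and computes TR phylogenies under an edit distance
    with unit duplication and contraction (EDDC). Includes seeded
    generators for synthetic complex TR haplotypes, slippage-driven
    populations, and HiFi-like reads so that every stage can be exercised
    without access to restricted human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
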