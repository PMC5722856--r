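Package: isodmb
Title: Integrative Analysis of Windowed DNA Methylation, Isochores, and
    Chromatin Accessibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for integrative epigenomic analysis built around
    iso-directional differentially methylated blocks (isoDMBs): windowed
    two-group differential methylation testing with an exact
    negative-binomial test, significance-threshold selection via the
    merged-DMR/DMR ratio and its analytic lower bound, segmentation of
    same-direction differentially methylated windows into blocks,
    Monte Carlo-Wilcoxon signed-rank bias tests of coordinated expression
    change, GC-isochore segmentation and classification, Jaccard
    interval-overlap tests with location shuffling, isochore-guided
    differential chromatin accessibility (DAI) analysis with permutation
    and clustering tests, and a seeded multi-omics count simulator so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    edgeR,
    optparse
Config/testthat/edition: 3
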