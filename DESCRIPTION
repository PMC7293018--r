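Package: tssanchor
Title: TSS-Anchored Positional Analysis of Transcription-Factor Binding at
    CpG-Island Promoters
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying where a transcription factor binds relative to
    transcription start sites and what that position implies for regulation.
    Implements strand-aware nearest-TSS annotation of ChIP-seq peaks, CpG-island
    promoter classification, TSS-anchored signal matrices with K-means
    positional clustering and tag-density mode detection, width-matched
    randomized-background motif coverage analysis (including ChIP-exo and
    summit-window modes), per-clone differential-expression consensus
    intersections with binding integration, and promoter methylation
    delta-beta classification. A fully seeded synthetic-data generator
    produces a toy genome with CpG-island promoters, positional peak mixtures,
    planted motifs, negative-binomial expression counts and methylation probe
    intensities, so that every stage of the analysis is testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
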