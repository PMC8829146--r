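Package: etmnet
Title: Endogenous Target Mimic Detection and miRNA-lncRNA-mRNA Network Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds miRNA-lncRNA-mRNA regulatory networks for plant
    transcriptomes. Detects candidate endogenous target mimics (eTMs) of
    miRNAs in lncRNA transcripts with an explicit complementarity rule
    engine (seed pairing, positionally constrained bulges, a cap on
    mismatches plus G:U wobbles), ranks features by the tau
    tissue-specificity index, predicts cis- (genomic window) and trans-
    (expression correlation) acting lncRNA targets, filters differential
    expression tables by adjusted p-value and fold-change thresholds, and
    assembles the results into a typed tripartite network. Includes a
    synthetic-data generator that plants known eTM sites, tissue-specific
    expression profiles, genomic distances and correlated pairs so every
    stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
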