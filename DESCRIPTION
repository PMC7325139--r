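Package: coldsrna
Title: Cold-Responsive Small RNA Classes, Targets and Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for time-resolved small-RNA and mRNA
    expression under cold acclimation. Provides negative-binomial
    differential expression with Benjamini-Hochberg correction and a
    four-state status call, reads-per-million size profiles per sRNA
    class, penalty-based miRNA target scoring with an expectation
    cutoff and optional target-site accessibility filtering,
    correlation-based classification of miRNA:mRNA and natural
    antisense transcript (NAT) pairs, detection of classical
    nat-siRNA regulons, hypergeometric term over-representation
    analysis, and a tiered miRNA-transcription-factor regulatory
    network with Louvain-style module detection and predictive-power
    validation by gradient-boosted regression. A synthetic-data
    generator emulates the full study design (two conditions, three
    time points, replicated negative-binomial counts with planted
    effects) so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    xgboost,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
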