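Package: duetseq
Title: Combinatorial Transcription-Factor Dependency Analysis for
    ChIP-seq and Factorial Mutant Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect how two interacting transcription factors
    regulate their targets individually and as a complex, using a 2x2
    genetic design (wild type, two single mutants, double mutant).
    Implements factorial signal-allocation of log2 expression into
    single-factor and interaction terms with empirical-Bayes moderated
    statistics and Storey q-values; reciprocal ChIP peak-dependency
    classification (ubiquitous / one-factor / two-factor regions) with a
    local-Poisson peak caller and replicate-reproducibility filtering;
    shape-based differential binding via functional principal component
    scores and Hotelling's T2; position-weight-matrix scanning with
    exact p-values and permutation Z-score motif enrichment; and a
    ground-truth synthetic-data generator (genome, gene models, planted
    motifs, replicate ChIP coverage, factorial expression matrices) so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    MASS,
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
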