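Package: condregulon
Title: Conditional Regulon Discovery for Expanded Transcription Factor Families
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrative analysis of how duplicated transcription factors
    (such as the archaeal feast/famine regulatory proteins, Lrp/AsnC family)
    diverge in function and context. Assigns ChIP-derived binding sites to
    target genes through strand-aware promoter windows with operon
    propagation, quantifies binding-map overlap, converts type-I functional
    divergence coefficients into clusterable distances, scores effector-
    preference residue profiles with BLOSUM62, and -- at its core -- detects
    condition-dependent activation or repression of a factor's targets by
    testing the median factor-target expression correlation within each
    environmental condition set against a permutation null of random gene
    sets. Includes deletion-strain validation statistics, growth-curve
    parameter extraction with a t-test/Bonferroni/Stouffer comparison ladder,
    multi-evidence network assembly, and a synthetic-data generator with
    planted conditional regulons so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    ape,
    igraph,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
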