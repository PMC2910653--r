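Package: retromark
Title: Retroposon Presence/Absence Phylogenetics and Nested-Insertion Chronology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phylogenetic analysis with retroposon (SINE) insertion
    markers. Reads RepeatMasker-style repeat annotations, detects
    transposition-in-transposition (TinT) nesting events between repeat
    families, and estimates relative family activity periods by maximum
    likelihood. Represents presence/absence marker matrices over taxa,
    validates candidate markers against orthologous-locus alignments,
    infers rooted trees under irreversible (gains-only) parsimony with
    random-addition heuristic search and TBR branch swapping, and computes
    the multinomial insertion significance test for marker support
    patterns. Includes a synthetic-data generator that simulates
    retroposon families inserting along a species tree with ground-truth
    ledgers, and ships a transcription of a published 21-taxon x 53-marker
    marsupial presence/absence matrix as a worked example.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
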