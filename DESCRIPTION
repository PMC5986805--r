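Package: ampliscreen
Title: In Silico Evaluation of Short-Amplicon Metabarcoding Primers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to evaluate degenerate metabarcoding primer sets on barcode
    reference databases: in silico PCR with explicit primer-fit criteria
    (mismatch budget and 3' anchor), taxonomic coverage and amplicon-length
    summaries by taxon, prefix-dereplication and taxonomic resolution at
    species/genus/family ranks, a greedy-centroid clustering threshold sweep
    for MOTU-based identification, closest-match taxonomic assignment with
    tie promotion, and amplicon length-bias diagnostics with a rank-sum test.
    Includes a synthetic ITS2-like reference-database and read simulator with
    planted ground truth so every pipeline stage is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
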