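Package: liposcan
Title: Sequence-Based Metagenomic Screening for Lipolytic Enzymes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profile hidden Markov model construction and scanning for
    lipolytic enzyme families, a two-tier annotation decision engine that
    combines profile-HMM and Smith-Waterman similarity evidence, LPGM
    (lipolytic hits per gigabase per million genes) abundance
    normalization, and habitat-comparison statistics (Bray-Curtis
    dissimilarity with Ward clustering, ANOSIM, point-biserial indicator
    associations and habitat-genus bipartite networks). Ships seeded
    synthetic-data generators so the whole screening pipeline can be
    exercised and validated without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    Biostrings,
    igraph,
    ape,
    vegan,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
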