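Package: cas13screen
Title: Design and Analysis of Pooled CRISPR-Cas13d Knockdown Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for pooled CRISPR-Cas13d RNA-knockdown
    proliferation screens. Covers crRNA library design with staged relaxation
    of quality criteria, mismatch- and coverage-aware off-target scanning with
    an exhaustive oracle, flank-anchored guide counting from reads, library
    evenness and replicate-correlation quality control, negative-binomial
    guide testing with alpha-robust-rank-aggregation gene scoring and
    permutation false discovery rates, allele-specific RNA half-life
    estimation from transcription-shutoff time courses, and RNA pull-down
    enrichment filtering. A synthetic-data module generates every input the
    pipeline consumes, with ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
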