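Package: citescreen
Title: Embedding-Based Active Learning for Systematic-Review Citation Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates and evaluates relevance-feedback prioritisation of
    title/abstract records during systematic-review screening. Articles and
    words are embedded jointly (skip-gram with negative sampling for words,
    distributed bag-of-words paragraph vectors for documents); their product
    forms a sentence-word feature matrix, and screening proceeds by cosine
    ranking against a query vector updated from researcher feedback, starting
    from two known-relevant seed articles. Includes readers for MEDLINE/nbib,
    RIS, CSV/TSV and JSONL reference exports, a synthetic labelled-corpus
    generator with a tunable topic-separation knob, retrospective evaluation
    (recall curves, work saved over sampling, per-step AUROC), and exhaustive
    seed-pair sweeps.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
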