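Package: debunkr
Title: Measuring the Effectiveness of Rumor-Debunking Methods from Comment Stances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how effectively different rumor-debunking
    strategies work on social media. Reply comments to debunking postings are
    classified into the four SDQC stances (supporting, denying, querying,
    commenting); per-group stance tallies yield a denial index (DI), a
    redundancy index (RI), and their ratio, the debunking effectiveness index
    (DEI). The package provides corpus containers with JSONL/CSV
    serialization, Cohen's kappa inter-annotator agreement, a lightweight
    trainable stance-classification baseline with macro-F1 evaluation,
    Kruskal-Wallis and Dunn-Bonferroni comparisons of per-posting indices
    across methods, decomposition of combination debunking methods into
    pair/triple signatures with graph export, a seeded synthetic-corpus
    generator with analytic ground truth, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
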