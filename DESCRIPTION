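Package: termscreen
Title: Weighted Keyword Term Scoring for Systematic Review Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for preliminary title and abstract screening in large-scale
    systematic reviews. Implements an expert-weighted positive/negative keyword
    registry, a term-scoring formula that ranks bibliographic records by
    weighted keyword match density, hard-exclusion rules (missing DOI, missing
    or short abstract, ineligible article type), ranking evaluation statistics
    (top-quartile eligible fraction, Spearman rank correlation, recall-at-effort
    curves, workload estimation), seed/test splitting and seed-file export for
    semi-automated screening tools, a screening simulator with a transparent
    nearest-centroid reference ranker in rank-once and active-learning modes,
    and a synthetic labelled-corpus generator with class-dependent keyword
    planting for end-to-end testing without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    stringi,
    rlang,
    jsonlite,
    ggplot2,
    Matrix,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
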