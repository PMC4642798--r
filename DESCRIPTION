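Package: vapewatch
Title: Infoveillance of E-Cigarette Marketing and Use on Twitter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for surveillance of e-cigarette conversations in
    tweet corpora. Filters a corpus to e-cigarette topics with an editable
    keyword syntax, extracts hashtags and (unshortened) links, classifies
    tweets as advertising or nonadvertising with binary n-gram and account
    metadata features (tree-importance feature selection followed by a small
    random forest, scored by stratified cross-validation), recovers physical
    places of e-cigarette use from nonadvertising tweets by rule-based
    prepositional-phrase chunking over part-of-speech tags, and computes
    marketing-surveillance aggregates: time series by class, retweet,
    promotion and brand shares, most active handles, most shared links, and
    follower-growth burst flags. Ships a seeded synthetic tweet generator so
    the full pipeline is testable without access to proprietary Twitter data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    Matrix,
    purrr,
    ranger,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
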