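Package: voicedistress
Title: Frame-Level Classification of Psychological Distress from Telephone Speech
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting psychological distress in
    telephone-band speech. Reads mono call audio with Audacity-style segment
    annotations, extracts a per-frame acoustic feature set (formants, Wiener
    entropy, harmonicity, spectral shape and sequence-context measures),
    screens correlated features, fits a penalized binomial generalized
    additive mixed model with sex-moderated smooths and caller random
    intercepts to select predictors, augments frames with k-means cluster
    principal components, classifies frames by component-wise gradient
    boosting with leave-one-caller-out validation and Youden-J thresholding,
    and aggregates frame probabilities to segment-level decisions. A
    synthetic-call generator (feature tables and raw source-filter audio)
    emulates the study design so every stage is testable without
    confidential recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    splines,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    mgcv,
    pROC,
    caret,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
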