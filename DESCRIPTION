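Package: borutafc
Title: Boruta Feature Selection and SVM Classification of Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds whole-brain interregional functional-connectivity feature
    tables from region-of-interest (ROI) time series, selects group-relevant
    connections with an all-relevant (Boruta-style) shadow-feature procedure,
    classifies subjects with a support vector machine under leave-one-out
    cross-validation, assesses significance by label-permutation testing, and
    summarises the selected connections by region/network classification
    weights, network degree, and k-means connection patterns, with
    brain-behaviour correlation of per-connection classification scores.
    Includes a synthetic-data generator that emulates the assumed statistical
    structure (six-network atlas, sparse discriminative connections, linearly
    linked clinical scales) so the whole pipeline can be exercised and
    validated without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
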