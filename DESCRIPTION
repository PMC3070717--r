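Package: xplatde
Title: Cross-Platform Common Differential Expression for Multi-Platform Microarray Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for discovering genes that are
    commonly differentially expressed across all samples, groups and
    platforms of a pooled single-channel microarray study. Covers
    CodeLink-style raw-spot quality filtering and background correction,
    global-median normalization, log-ratio computation against the control
    mean, cross-platform harmonization by NCBI Gene ID intersection and
    quantile normalization, four differential-expression comparison modes
    (group t-tests against controls, per-sample intra-experimental z-tests,
    per-gene inter-experimental z-tests), Storey q-value false discovery
    rate estimation, set-algebra commonality reports (simultaneous
    direction sets, group-pair combinations, combined intra/inter cases,
    incidence ranking, tolerant group-common markers), chromosome-level
    summaries and correlation maps, hypergeometric over-representation of
    annotation terms, and a seeded synthetic-data generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
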