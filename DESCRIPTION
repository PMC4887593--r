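Package: tsevents
Title: Event-Based Similarity, Reference Models and Classification for
    Biomedical Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining events from fixed-rate biomedical time series
    such as electroencephalograms and force-plate posturography. Provides a
    declarative event-definition language (relative-amplitude waves such as
    spikes, sharp waves and spicules; absolute-threshold excursions such as
    falls), cleaning rules for missing and inconsistent samples, a Dice-style
    agreement metric between expert and detected event sets, event-matching
    similarity between series and between hierarchically modelled subjects,
    per-class reference models built by clustering events with similarity-based
    outlier screening, maximum-similarity classification with stratified k-fold
    cross-validation, and a seed-deterministic synthetic cohort generator with
    planted ground-truth events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
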