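Package: scmseq
Title: Scoring Card Method for Interpretable Protein Sequence Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the scoring card method (SCM), an interpretable binary
    classifier for protein sequences built on dipeptide propensity scores.
    A scoring card assigns each of the 400 ordered dipeptides a propensity
    score in [0, 1000]; a sequence is scored by the composition-weighted mean
    of its dipeptide scores and classified against a threshold. The initial
    card is estimated from class composition differences and refined with a
    seeded real-coded genetic algorithm maximizing a weighted combination of
    cross-validated AUC and the correlation between initial and refined
    amino-acid scores. Includes stratified cross-validation, ROC/AUC
    evaluation, propensity-score analysis against physicochemical property
    scales (AAindex-style tables), positional score profiles, heat-map and
    histogram summaries, and a first-order Markov generator of synthetic
    two-class sequence datasets with planted dipeptide-composition signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
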