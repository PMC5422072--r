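Package: dcmlip
Title: Sequential Sensory and Decision Signal Analysis for Delayed-Conjunction-Matching Spike Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for trial-aligned extracellular spike recordings
    from delayed-conjunction-matching (DCM) visual search tasks, as recorded in
    posterior parietal cortex (area LIP). Provides a trial/event/spike data
    model with lossless tabular and binary storage, a task-driven
    inhomogeneous-Poisson spike-train simulator spanning the continuum from
    identity-selective to match-selective neurons, randomized spike decimation
    for condition equalization, sliding-ROC selectivity and onset-latency
    estimation with a visuo-decision index, pseudo-population linear-SVM
    decoding with bootstrap significance, permutation tests for laterality of
    match signals, conjunction-additivity decomposition, feature-based-attention
    tuning-shift measurement, and choice-probability analysis relating firing
    dynamics to reaction times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
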