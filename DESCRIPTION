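Package: instrudecode
Title: Decoding Outcome and Response Representations During Instrumental
    Learning from EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for EEG-based multivariate
    decoding of outcome and response representations during instrumental
    learning under an outcome-devaluation paradigm.  Provides a generative
    model of the behavioural task (a softmax mixture of a goal-directed,
    value-based controller and an incremental stimulus-response habit
    controller) and of category-specific EEG epochs; an epoch container
    with HDF5 serialization, baseline correction and resampling; a
    sliding-window linear-SVM decoding pipeline with leave-one-out window
    selection, adjusted-Wald chance thresholds, cross-task application and
    block aggregation; event-related-potential summaries (occipital P1,
    late centroparietal time bins); a channel-space searchlight; and
    behavioural devaluation summaries with Spearman and Bayes-factor
    correlation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    rhdf5,
    signal,
    stats,
    utils,
    yaml
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
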