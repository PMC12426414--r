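Package: tmsreact
Title: Resting EEG and TMS-EEG Cortical Reactivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for resting-state EEG and TMS-evoked EEG
    (TMS-EEG) in studies of cortical reactivity, built around the measures used
    in theta-burst and 10-Hz repetitive TMS trials: Welch relative band power
    over the delta/theta/alpha/beta/gamma partition and the (delta+theta)/
    (alpha+beta) slowing ratio, phase-lag-index functional connectivity,
    TMS-evoked-potential processing (epoching, artifact-window interpolation,
    amplitude-based trial rejection, global mean field amplitude, local motor
    cluster potentials, P30/N45/P60/N100/P180 peak quantification),
    UPDRS-III-based responder labelling, and a nested cross-validated linear
    SVM responder classifier. A synthetic-data module generates resting
    recordings with controlled band power and phase-lagged channel pairs, TEP
    epochs with planted components, stimulation protocols, and cohorts with
    known ground truth, so the entire pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
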