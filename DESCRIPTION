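Package: gazecue
Title: Gaze-Cueing Analysis of Early-Stage Attentional Orienting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for gaze-cueing experiments
    with concurrent eye tracking, aimed at characterising early-stage
    attentional orienting in children with ADHD versus typically developing
    peers. Provides a synthetic-cohort generator (task schedules,
    group-conditioned gaze streams, behavioural responses, questionnaire
    covariates), Savitzky-Golay smoothing and velocity-threshold (I-VT)
    fixation/saccade segmentation, per-trial oculomotor features including
    response-to-joint-attention and peripheral-vision detection,
    participant-level aggregation with gaze-cueing effects and eligibility
    filtering, a mixed-model plus Mann-Whitney/Benjamini-Hochberg screening
    funnel, and stepwise logistic classification with Rao score tests and
    repeated stratified cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    signal,
    lme4,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
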