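Package: rtcit
Title: Simulation and Analysis of Reaction-Time Concealed Information Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the Go/No-go reaction-time Concealed Information Test
    (RT-CIT): a calibrated trial-level simulator of the paradigm (ex-Gaussian
    reaction times, no-go commission errors, Likert questionnaire items and
    post-test ratings), preregistered-style trial and participant exclusion
    rules, per-participant RT-CIT effect and dCIT scoring, LSRP and BIS-11
    scale scoring with Cronbach's alpha, detection-efficiency estimation by
    bootstrap ROC/AUC against a simulated naive group, and default Bayes
    factors (JZS one-sample t test, stretched-beta Pearson correlation) with
    sequential evidence trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    jsonlite,
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
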