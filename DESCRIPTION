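Package: gaitphase
Title: Gait-Phase Classification and Gait-Event Prediction from Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies gait phases (stance vs. swing) and predicts
    heel-strike and toe-off timing from multi-channel surface
    electromyography (sEMG) recorded during walking. Raw signals are
    band-pass filtered, rectified, low-pass enveloped and min-max
    normalized, cut into short multi-channel windows, and fed to a
    multi-layer perceptron trained with early stopping; the predicted
    binary foot-floor-contact signal is cleaned by minimum-phase-duration
    filtering and scored against foot-switch ground truth with
    tolerance-based event matching (precision, recall, F1, mean absolute
    timing error). Includes a synthetic gait/EMG simulator, intra-subject
    10-fold and inter-subject leave-one-subject-out protocols, and a
    Shapiro-Wilk-gated statistical comparison between the two approaches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
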