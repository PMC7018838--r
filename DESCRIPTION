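Package: gazekit
Title: Head-Free Gaze Kinematics, Event Metrics and Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing eye and head coordination when the head is
    free to move. Converts synchronized eye-in-head direction vectors and
    head orientations into filtered angular velocity signals (two-point
    central difference, Kaiser-window zero-phase anti-aliasing, bilateral
    smoothing), represents and cleans gaze-event label sequences over the
    fixation/pursuit/saccade taxonomy, and scores agreement between label
    sequences at the sample level (Cohen's kappa, precision/recall/F1) and
    the event level (majority vote, event F1 with relative timing offsets,
    largest-overlap event kappa, event error rate, and the window-based
    Event Level Cross-Category metric with timing-offset correction).
    Includes windowed-feature Random Forest and GRU sequence classifiers
    with leave-one-subject-out evaluation, and a seeded generator of
    labelled synthetic head-free recordings for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    ranger,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
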