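Package: brainstates
Title: Dynamic Brain States of Consciousness from Network Time Courses
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sliding-window dynamic functional connectivity analysis that
    discriminates conscious from unconscious brain recordings. Computes
    windowed inter-network correlation matrices from standardized network
    time courses, clusters them into recurring patterns of global brain
    communication with L1 (Manhattan) k-means, derives state occupancy and
    transition dynamics, classifies consciousness with Fisher-score feature
    ranking and a linear support vector machine across independent cohorts,
    and relates per-network activity to the occurrence of consciousness-
    specific patterns by logistic regression. Includes a synthetic
    state-switching cohort generator with full ground truth, a spectral
    signal/noise component screening rule, and time-course conditioning
    (despiking, zero-phase Butterworth filtering, sliding-mean smoothing).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
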