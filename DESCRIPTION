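Package: gistsdt
Title: Signal Detection Analysis of Gist-of-Abnormality Rating Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for rating-scale (0-100) perceptual studies of the
    rapidly extracted "gist of abnormality" in unilateral mammograms. Computes
    hit and false-alarm rates, d-prime and criterion with extreme-proportion
    correction, empirical sliding-threshold ROC curves and kernel-smoothed
    log-likelihood-ratio ROC curves with bootstrapped above-chance tests,
    classifies perceptual-learning trajectories into learners and non-learners,
    and reproduces the random-rater simulation null for that split. Includes a
    full synthetic-experiment generator (stimulus pools, training schedules with
    attention trials, an adaptive maximum-viewing-time staircase, and parametric
    signal-detection observers) so every analysis stage can be exercised without
    human or image data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
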