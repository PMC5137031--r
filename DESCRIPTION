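Package: ecgaze
Title: Scan-Path and Markov-Chain Analysis of ECG Interpretation Eye Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing eye-tracking data collected while clinicians
    interpret 12-lead electrocardiograms. Fixation-event exports are mapped
    onto areas of interest (AOIs) covering the ECG leads and rhythm strips,
    producing per-participant scan paths. Gaze-shift behaviour of correct
    and incorrect interpretation groups is compared by pooling lead-to-lead
    transition counts, estimating additively smoothed first-order Markov
    chains, and measuring the Jensen-Shannon distance between the two
    chains; significance is assessed with a group-label permutation test.
    Also includes per-lead fixation descriptives, n-gram profiling of scan
    paths, and a synthetic-cohort generator with known transition kernels
    for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
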