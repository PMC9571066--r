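Package: morphripple
Title: Morphological Spike Removal and Dynamic Thresholding for Ripple
    Detection in Intracranial EEG
Version: 0.1.0
Authors@R:
    person("morphripple", "developers", email = "morphripple@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting high-frequency oscillations ("ripples",
    80-250 Hz) in intracranial EEG and for rejecting the false detections
    caused by interictal spikes and sharp transients. Implements exact
    one-dimensional flat grayscale morphology (erosion, dilation, opening,
    closing) with an O(n) sliding-extrema fast path and a brute-force
    oracle, an RMS-envelope candidate detector in the style of classical
    ripple detectors, a spike-versus-ripple classifier based on a dynamic,
    spike-shape-dependent threshold derived from morphological opening of
    the smoothed rectified first difference, an event-level
    sensitivity/false-detection-rate/ROC evaluation layer with repeated
    stratified cross-validation, a seeded synthetic iEEG generator with
    ground-truth event tables, and CSV/EDF input-output plus a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
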