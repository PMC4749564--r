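Package: prehensr
Title: Tracking and Analysis of Skilled Forelimb Prehension in Head-Fixed Mice
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tools for the quantitative analysis of cued, multi-step forelimb
    prehension (reach, grab, retrieve) in head-fixed mice under optogenetic
    cortical perturbation. Provides a cascaded-pose-regression hand tracker for
    high-speed stereo video with multi-initialization mode finding, dynamic
    programming trajectory smoothing and error-frame flagging; calibrated
    pinhole stereo triangulation with per-animal calibration refinement;
    ethogram (behavioral epoch) validation and latency statistics, initiation
    rates and cumulative first-lift histograms; trajectory statistics comparing
    cued, laser-perturbed and rebound reaches (distance-to-target time courses
    with matched controls, interquartile divergence times, arc-length alignment
    and nearest-neighbor balanced accuracy, grab end-point error); spike-train
    analysis (trough-to-peak width classification, peristimulus time
    histograms, suppression and rebound quantification); and a synthetic-data
    generator producing trials, stereo videos and spike trains with the
    statistical structure these analyses assume, so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml,
    png,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
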