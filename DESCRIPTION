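Package: atseg
Title: Anaerobic Threshold Detection from Cardiopulmonary Exercise Tests
    by Structural-Change Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Objective detection of the ventilatory anaerobic threshold (AT)
    from ramp cycle-ergometer cardiopulmonary exercise tests. Breath-by-breath
    ventilation channels are averaged into 10-second bins, smoothed with a
    3-point moving average, and segmented by multiple-structural-change
    regression: an exact dynamic-programming search over piecewise linear
    fits with a minimum segment length, BIC selection of the number of
    breakpoints, and asymptotic 95% confidence intervals for each break date.
    The detected break is mapped onto the ergometer load (watts) through the
    ramp protocol. An algorithmic V-slope baseline (two-limb regression of
    carbon dioxide output on oxygen uptake), a synthetic breath-by-breath
    generator with known ground-truth threshold, and agreement/reliability
    statistics (confidence-interval containment counts, ICC(2,2) with a
    Shrout-Fleiss lower confidence bound) complete the pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
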