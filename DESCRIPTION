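Package: loomhab
Title: Habituation of Looming-Evoked Escape Behavior and Its Neural Correlates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Stimulus generation and analysis tools for studying habituation of
    visually evoked escape behavior in larval zebrafish. Generates looming,
    dimming, brightening and checkerboard-loom stimuli from the l/|v| angular
    size law together with their luminance profiles and calcium regressors;
    detects tail-flick escape events from tracking traces and computes
    Poisson-corrected response probabilities and exponential habituation
    curves; assigns each imaged neuron a 4-bit stimulus-tuning code from
    trial-averaged regressor correlations; fits per-cell exponential amplitude
    dynamics and classifies cells as depressing, potentiating or stable via
    double-Gaussian rate thresholds; computes hemispheric and binocularity
    indices and GABAergic calls from red-channel ROI overlap. A synthetic-data
    generator with full ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
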