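Package: pcwa
Title: Parallel Cluster Wavelet Analysis for Single-Particle Sensor Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fast, cluster-based continuous wavelet transform (CWT) event
    detection for time traces from single-molecule and single-particle
    sensors. Implements the Parallel Cluster Wavelet Analysis (PCWA)
    detector: per-scale local maxima of the CWT map are grouped into macro
    clusters along the time axis and resolved into star-graph micro
    clusters by an ellipse-overlap rule, yielding one event per cluster
    with its time, temporal scale and coefficient. Includes a custom
    Multi-Spot Gaussian (MSG) mother wavelet matched to multi-peak signals
    from multi-spot (multi-mode interference waveguide) excitation,
    Ricker and real Morlet wavelets, baseline detectors (amplitude
    threshold, shift-multiply, ridge-line CWT), peak-number classification
    with velocity and intensity extraction, a Poisson shot-noise trace
    simulator with ground truth, and an evaluation harness (event
    matching, ROC curves, method comparison tables, runtime scaling).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
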