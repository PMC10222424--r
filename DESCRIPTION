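Package: uniecg
Title: Single-Position ECG Feasibility Analysis with a FitzHugh-Nagumo
    Cardiac Phantom
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the feasibility of single-electrode
    ("single-position") electrocardiography against conventional two-point
    detection, entirely on simulated data. Provides a two-dimensional
    monodomain FitzHugh-Nagumo simulation of a heart-torso phantom with a
    full cardiac conduction system (sinoatrial node through Purkinje
    fibers), producing both a conventional differential surface lead and
    the smooth wave-like trace seen by a single charge-sensing electrode;
    a generator of device-like paired ECG recordings with realistic beat
    morphologies, baseline drift, powerline interference and
    posture-dependent noise; ECG filter chains; and a heart-rate-graph
    correlation analysis (QRS detection, instantaneous heart rate,
    Pearson correlation, extremum deviation, SNR estimation and
    signal-quality screening) for comparing the two detection modes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
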