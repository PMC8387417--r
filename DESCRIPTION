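Package: occupet
Title: Receptor Occupancy Analysis for Dynamic Small-Animal PET
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of dose-dependent receptor occupancy from
    dynamic PET studies with an image-derived arterial input function.
    Fits the two-tissue compartment model to brain time-activity curves by
    frame-duration-weighted nonlinear least squares, using a rise-then-
    three-exponential image-derived whole-blood input corrected for plasma
    partitioning and radiometabolites; derives binding potential (k3/k4) and
    distribution volumes; computes percent receptor occupancy against a
    median vehicle baseline and fits Hill-Langmuir dose-response curves;
    quantifies tracer uptake as percent injected dose per gram and ex vivo
    autoradiography intensities normalized to an internal muscle control.
    Includes a synthetic-cohort generator emulating a two-genotype,
    four-dose study design, and the matching stratified nonparametric test
    battery (exact Wilcoxon rank-sum, van Elteren, linear-by-linear trend,
    cluster-robust log-link regression).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    sandwich,
    lmtest,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
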