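Package: tracescore
Title: Signal-Detection Scoring and Stimulus Synthesis for Edge-Tracing
    Psychophysics
Version: 0.1.0
Authors@R:
    person("Trace", "Score", email = "maintainer@tracescore.dev",
           role = c("aut", "cre"))
Description: Toolkit for edge-tracing experiments on noisy natural images:
    synthesis of calibrated broadband (white, pink, brown) and narrowband
    visual noise masks, RMS-contrast normalization and stimulus compositing,
    signal-detection scoring of binary edge-trace maps against per-observer
    ground truths with a pixel error margin (proportion correct, d-prime,
    response bias), max-scaled cumulative-Gaussian psychometric fits with
    threshold extraction, consensus-heatmap patch sampling with luminance,
    contrast and directional power-spectrum statistics, and a synthetic
    scene and observer simulator so the full pipeline is testable without
    any experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    optparse,
    png,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
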