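Package: boolcortex
Title: Threshold Boolean Network Dynamics on Brain Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates windowed-threshold Boolean dynamics on weighted brain
    connectomes. Provides loading, validation, thresholding and synthesis of
    82-region Brodmann-style connectomes; synchronous and asynchronous update
    schemes (CRBN, ARBN, DARBN, GARBN, DGARBN); transient and period detection
    with dynamical-regime classification; extraction of emergent "brain
    circuits" by Pearson correlation thresholding of node time series, with
    intersection and subset analysis; parameter sweeps over the activation
    window and thresholds with stability scoring against a reference circuit
    configuration; and a command-line workbench tying the pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
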