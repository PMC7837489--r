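Package: photokin
Title: Light-Modulated Behavior and Gene Expression Analysis for Larval Fish Assays
Version: 0.1.0
Authors@R:
    person("photokin", "developers", email = "photokin@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for visuo-motor and photic behavior assays in larval
    and juvenile fish: emission-spectrum photon-flux computation and Michelson
    contrast, moving-dot avoidance-index scoring with size-tuning curves and
    total-avoidance summaries, binned locomotor activity with per-interval area
    under the curve for photokinesis and diel light schedules, normalized fast
    dark-photokinesis responses, a normality-gated two-sample statistical decision
    tree with exact small-sample Mann-Whitney tests, and qPCR relative
    quantification normalized to a reference gene. A synthetic-data module
    generates trajectories, dot-interaction events and qPCR plates with the
    statistical structure the analyses assume, so the whole pipeline is testable
    without raw tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
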