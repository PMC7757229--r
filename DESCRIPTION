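Package: coccobloom
Title: Detection of Coccolithophore Blooms from BGC-Argo Float Bio-Optics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end detection of coccolithophore blooms from autonomous
    profiling-float bio-optical measurements. Quality-controls raw float
    profiles (despiking, transmissometer fouling-drift correction,
    non-photochemical quenching correction, chlorophyll calibration,
    mixed-layer depth), composites daily ocean-colour satellite calcite
    fields along float trajectories into gap-free matchup series, labels
    bloom periods on the particulate-inorganic-carbon time series, derives
    optical classification thresholds by ROC analysis, and classifies float
    profiles with a dual backscattering-to-chlorophyll plus backscattering
    rule. Includes a synthetic-ocean generator that emulates the seasonal
    diatom-then-coccolithophore succession, cloud gaps, quenching,
    transmissometer fouling and optical spikes, so the whole pipeline is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    zoo,
    geosphere
Suggests: testthat (>= 3.0.0), jsonlite, knitr, ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
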