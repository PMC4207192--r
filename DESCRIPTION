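Package: cpmcassay
Title: Quantification and Translational Scoring of an In Vitro Colonic
    Motility Bioassay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates intraluminal-pressure recordings of mouse colonic
    peristaltic motor complexes (CPMCs) with concentration-dependent drug
    effects, detects CPMC events and computes the five per-phase motility
    metrics (frequency, inter-complex interval, time in quiescence, amplitude,
    area under the curve), applies the vehicle-relative two-standard-deviation
    decision rule against time-matched controls, and scores translational
    concordance (TP/FP/TN/FN and predictive capacity) of both the in vitro
    assay and the in vivo charcoal-meal transit assay against clinical
    gastrointestinal adverse drug reaction labels within a 50-fold exposure
    window.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
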