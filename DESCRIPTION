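Package: afmforce
Title: AFM Force-Spectroscopy Analysis of Protein-Drug Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for atomic-force-microscopy (AFM) force
    spectroscopy of protein layers: conversion of deflection-signal traces to
    force-distance curves via Hooke's law, baseline correction and adhesion
    (unbinding) force extraction from retraction segments, Gaussian peak and
    box-plot summaries of force ensembles, Poisson step analysis decomposing
    adhesion into specific per-bond and non-specific force components through
    the variance-mean regression, friction-loop half-width analysis with
    lateral force calibration, and surface topography metrics (average height,
    Sa, Sq) from leveled height maps. A synthetic-data generator with known
    ground truth (Poisson-distributed bond counts, piecewise-linear curves,
    symmetric friction loops, Gaussian-bump topographs) makes every stage
    testable without instrument data, and a sweep driver aggregates all
    metrics across drug and electric-field conditions into a report with
    percent reductions and significance stars.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
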