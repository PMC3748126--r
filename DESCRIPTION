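Package: myotubeHCS
Title: High-Content Quantification of Myotube Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying skeletal-muscle myoblast differentiation in
    high-content screens of multiwell plates. Segments Troponin-T-positive
    myotubes and DAPI-stained nuclei from two-channel fluorescence fields,
    computes per-myotube morphometry (area, perimeter, Feret length and
    breadth, integrated intensity, nuclei per myotube), assigns nuclei to
    myotubes by outline containment, derives well-level summaries including
    the myogenic fusion index, and runs the associated statistical battery
    (t-tests, one-way ANOVA with Tukey comparisons, two-way factorial ANOVA
    with interaction tests and multiplicity correction). Includes a synthetic
    plate renderer with per-object ground truth for validating the pipeline
    end to end.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    tiff,
    yaml,
    car,
    emmeans,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
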