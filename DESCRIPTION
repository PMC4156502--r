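Package: switchfit
Title: Kinetic Modeling of Transcription and mRNA Decay from Paired Time
    Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Disentangles transcriptional from mRNA-decay contributions to
    gene-expression dynamics. Fits per-gene first-order kinetic models to
    paired relative transcription-rate (e.g., RNA polymerase II occupancy)
    and mRNA-abundance time courses: a 'constant' decay-rate model and a
    piecewise 'switch' model in which the decay rate changes instantaneously
    at an estimated time, with model selection by adjusted R-squared and
    inference of decay-rate shifts (stabilization or destabilization).
    Includes a synthetic-cohort generator with ground truth, profile
    statistics (maximum fold changes, correlations, response timing),
    correlation-based hierarchical clustering, regulatory-strategy and
    regulator-dependence classification, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    graphics,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
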