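Package: testune
Title: Mechanistic Modelling and Characterization of Tunable Expression Systems
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Deterministic, delay and stochastic models of a tunable expression
    system (TES) in which one promoter drives a toehold-switch mRNA and a second
    promoter drives a tuner small RNA that activates its translation, together
    with the flow-cytometry characterization pipeline used to quantify TES, NOT
    and NOR gate behaviour: density gating, autofluorescence correction,
    relative-promoter-unit (RPU) calibration, Hill response-function fitting,
    histogram-intersection statistics and device performance metrics. Includes a
    synthetic single-cell data generator with a truth manifest so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
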