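Package: irdose
Title: Dose-Response Modelling and Laser-Power Optimization for
    IR-Laser-Induced Single-Cell Recombination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for planning and analysing infrared-laser
    microirradiation experiments that trigger heat-shock-driven CRE/loxP
    recombination in single plant cells.  Implements standard and
    upper-bounded logistic dose-response models of recombination and
    cell-death probability as functions of laser power and target-cell
    size, maximum-likelihood and Markov chain Monte Carlo estimation with
    convergence diagnostics, likelihood-ratio tests for cell-size
    effects, composite-probability optimization of the laser power
    (single-cell and local-induction objectives), 10% raising points,
    and a calibrated synthetic-trial generator for validating the whole
    pipeline by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    coda,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    lmtest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
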