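Package: icisim
Title: Mechanistic Simulation of CD8+ T-Cell Immunity, Melanoma Growth and
    PD-1 Checkpoint Blockade
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ordinary-differential-equation model of the cellular immune
    response to an advanced melanoma under anti-PD-1 therapy
    (pembrolizumab).  CD8+ T cells are resolved on a differentiation-by-
    senescence grid (stem-cell memory through effector to exhaustion,
    with a replicative division counter), the tumor grows by a power law
    with exponent 2/3, and the drug lifts PD-1/PD-L1-mediated apoptosis
    and functional impairment.  The package bundles the simulator, a
    penalised root-mean-square calibration routine with profile
    confidence intervals, a synthetic tumor-load data generator with a
    CT measurement-error model, and virtual-patient trial machinery
    (population sampling, untreated-progression screening, irRECIST
    response classification and reinvigoration-based responder
    prediction).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
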