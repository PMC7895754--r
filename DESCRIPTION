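Package: macpol
Title: Mechanistic Simulation of Dynamic Macrophage M1-M2 Polarization
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A mass-action/Hill-kinetics ordinary-differential-equation engine
    for simulating dynamic macrophage M1-M2 polarization driven by a
    multi-pathway cytokine and oxygen-sensing signaling network. Ships a
    curated reduced seven-pathway reference network (IFN-gamma, TNF-alpha,
    IL-1beta, IL-4, IL-10, VEGF, hypoxia) with receptor trafficking,
    autocrine feedback, microRNA regulation and an M1-M2 marker panel;
    stimulation/intervention protocols; fold-change based M1/M2 phenotype
    scoring and polarization maps; Latin-hypercube/PRCC global sensitivity
    screening; virtual-cell population analysis; and scaled-down calibration
    with bootstrap uncertainty. Networks are read and written in a native
    JSON dialect and a supported SBML subset.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    xml2,
    yaml,
    digest,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
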