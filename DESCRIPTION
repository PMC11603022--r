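Package: fccstransport
Title: Dual-Color FCCS Analysis of Transporter-Mediated Lipid Exchange
    Between Vesicle Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model and analyse fluorescence cross-correlation
    spectroscopy (FCCS) assays of non-vesicular lipid transport between
    large unilamellar vesicle (LUV) populations by the yeast
    transporter Osh6. The package provides LUV geometry and assay
    scenario builders, a mass-action kinetic model of membrane
    adsorption, cargo (PS/PI4P) extraction, exchange and release, a
    biosensor binding-isotherm readout, a Brownian-dynamics photon-trace
    synthesizer for a two-channel confocal volume, multi-tau and direct
    correlation estimators with diffusion-model fitting, and the
    extraction/transport rate estimators with replicate statistics
    (outlier screening, SEM, two-sample t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
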