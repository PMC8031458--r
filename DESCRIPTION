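Package: soluthermo
Title: Temperature-Dependent Drug Solubility Correlation and Dissolution
    Thermodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the thermodynamic analysis of saturation shake-flask
    solubility studies of poorly water-soluble drugs in water and micellar
    surfactant solutions.  Computes mole-fraction solubility from raw masses
    or assay concentrations, ideal solubility from fusion calorimetry,
    correlates solubility-temperature data with the van't Hoff and modified
    Apelblat models (with percent RMSD and R-squared goodness of fit),
    performs apparent thermodynamic analysis at the mean harmonic
    temperature following Krug, combines Hansen solubility parameter
    components, and quantifies micellar solubilization capacity.  Includes
    a synthetic shake-flask data generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
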