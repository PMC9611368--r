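Package: aromafrac
Title: Fractionated Condensation of Organophilic-Pervaporation Permeates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Thermodynamic and material-balance modelling of aroma recovery by
    fractionated condensation of permeates from organophilic pervaporation.
    Given a characterised permeate stream (per-compound fluxes, inert-gas flow,
    permeate pressure) and compound properties (Antoine coefficients,
    infinite-dilution activity coefficients, odour thresholds), the package
    predicts the fraction of water and of each aroma condensing in each
    condenser of a series, the condensate compositions, and whether off-flavour
    concentrations in the first condensate fall below olfactive thresholds.
    Includes pervaporation performance metrics (molar flux, permeability,
    separation factor), a seeded synthetic-scenario generator with known ground
    truth, and a bundled sardine-cooking-wastewater example panel.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
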