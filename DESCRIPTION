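Package: scco2sol
Title: Solubility Modelling of Methyldopa in Supercritical CO2 with an
    Ethanol Cosolvent
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Correlates the equilibrium solubility of methyldopa in
    supercritical carbon dioxide, with and without an ethanol cosolvent,
    using the standard family of semi-empirical density models (Chrastil,
    Bartle, Kumar-Johnston, Mendez-Santiago-Teja, Sodeifian-Sajadian,
    Gonzalez, Soltani-Mazloumi, Jouyban, Garlapati-Madras) fitted by seeded
    simulated annealing, and with the Peng-Robinson equation of state under
    two-parameter van der Waals mixing rules. Ships the isothermal
    solubility tables as fixtures and provides enthalpy decomposition,
    cosolvent enhancement factors, crossover-pressure detection and a
    synthetic-data generator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
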