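Package: fermenet
Title: Integrated Flexible-Net Modeling of Genome-Scale Metabolism and
    Chemostat Bioreactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples a constraint-based (flux balance) metabolic model of a
    production organism with the macroscopic steady-state mass balances of a
    chemostat bioreactor inside a single Flexible Net: a tripartite net
    formalism whose event net carries reaction stoichiometry and whose
    intensity net sets reaction speeds from concentrations. The bilinear
    coupling between specific exchange fluxes and cell density is relaxed
    region-wise into a family of linear programs over a partition of the
    biomass range, and the best region gives the steady-state optimum.
    Includes readers for SBML Level 3 (fbc) and a plain JSON/TSV model
    dialect, chemostat specification and unit handling, volumetric and
    substrate productivity objectives, fixed-biomass prediction of tank
    concentrations, grid sweeps over feed concentration and dilution rate,
    a brute-force fixed-biomass oracle for validating the relaxation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    pracma,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
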