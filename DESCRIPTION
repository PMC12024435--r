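Package: aavmet
Title: Kinetic-Metabolic Modelling of rAAV Production in HEK293 Cells
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A Michaelis-Menten kinetic model of the central metabolism of
    HEK293 cells producing recombinant adeno-associated virus (rAAV) by
    triple transient transfection: 53 metabolite mass balances driven by 32
    enzymatic fluxes spanning glycolysis, the TCA cycle, the pentose
    phosphate pathway, anaplerosis, amino-acid metabolism, nucleotide and
    biomass synthesis, and AAV Rep/Cap protein synthesis. Provides stiff ODE
    simulation of metabolite profiles, Newton-Gauss-Levenberg/Marquardt
    nonlinear least-squares estimation of kinetic parameters and initial
    concentrations with a block-coordinate schedule, Sobol first-order
    global sensitivity analysis over the kinetic parameters, and a
    synthetic bioreactor-dataset generator for validating the fitting and
    sensitivity stages.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
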