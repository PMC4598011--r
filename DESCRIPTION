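Package: glymphsim
Title: Compartmental Simulation of Glymphatic Beta-Amyloid Clearance in the Aging Brain
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Deterministic three-compartment simulator of beta-amyloid (Abeta40
    and Abeta42) generation, microglial uptake, perivascular (glymphatic)
    convection, LRP-1 mediated transport across the blood-brain barrier, and
    deposition in a 1 mm^3 hippocampal tissue volume over decades of daily
    time steps. Includes cell-population aging dynamics (neurons, microglia,
    endothelial cells, LRP-1 receptor pool), a cumulative mass-balance flux
    ledger, scenario presets for heart-rate, vessel-stiffness, ApoE-allele and
    amyloid-generation perturbations, normalized endpoint reports, calibration
    of the free flow parameters against published endpoints, one-at-a-time
    sensitivity sweeps, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
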