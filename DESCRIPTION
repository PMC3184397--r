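Package: redoxrbc
Title: Kinetic Simulation of Redox Imbalance in G6PD-Deficient Erythrocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the antioxidant defence network of the human erythrocyte
    as a kinetic ODE model and scores redox imbalance after an oxidative
    (hydrogen peroxide) perturbation. Individual glucose-6-phosphate
    dehydrogenase (G6PD) variants are represented by their six kinetic
    parameters (Vmax, KmG6P, KmNADP, KiNADPH, KiATP, Ki2,3BPG); real reference
    subjects and Monte-Carlo virtual patients are run through a steady-state /
    perturbation / recovery protocol, and three indicators of redox imbalance
    (initial GSH/GSSG, recovery time, amount of change) are computed and
    related to the kinetic parameters across cohorts and parameter grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
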