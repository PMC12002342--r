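Package: magnetherm
Title: Magnetic Nanoparticle Hyperthermia Simulation for Skin Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation toolkit for magnetic fluid hyperthermia treatment
    planning on a nested-cylinder skin-tumor model. Computes the composition
    and gold-shell thickness of core-shell Fe3O4@Au nanoparticle ferrofluids
    from spectroscopic atomic ratios, the volumetric heating power of the
    suspension under an alternating magnetic field via Rosensweig linear
    response theory with combined Neel-Brownian relaxation, the on-axis and
    off-axis field of the excitation coil, the transient Pennes bioheat
    equation on an axisymmetric finite-volume grid with blood perfusion and
    metabolic sources, and Arrhenius thermal-damage kinetics over the
    resulting temperature histories. Includes single-parameter sensitivity
    sweeps over perfusion, blood properties, metabolic heat and nanoparticle
    power, plus a scenario generator for reproducible in-silico experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
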