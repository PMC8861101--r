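Package: synergyscreen
Title: Combination Viability Screens, Drug-Interaction Scoring and
    Metabolic Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for two-arm (drug versus vehicle) replicated
    384-well perturbagen viability screens: plate normalization against
    negative controls, Z'-factor quality control, replicate reproducibility,
    ratio-based hit calling with annotation-driven stratification, and
    coefficient-of-drug-interaction (CDI) synergy scoring with replicate-level
    significance testing.  Companion modules extract glycolysis and
    mitochondrial stress-test parameters from extracellular-flux (ECAR/OCR)
    traces, classify bioenergetic phenotypes, and estimate cell-cycle phase
    fractions from DNA-content distributions by constrained mixture fitting.
    A synthetic-data generator with known ground truth (multiplicative
    drug-by-perturbagen effects, plate and edge artefacts, log-normal well
    noise, four-phase flux traces, three-component DNA-content mixtures)
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    graphics,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
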