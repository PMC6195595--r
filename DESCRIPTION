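Package: nrpsdock
Title: Docking-Domain Interaction Analysis for Modular Megasynthases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of the short terminal docking domains (DDs) that mediate
    subunit pairing in non-ribosomal peptide synthetases (NRPS), modelled on the
    rhabdopeptide-producing Kj12ABC system from Xenorhabdus stockiae. Implements
    chemical-shift-perturbation (CSP) mapping of NMR titrations with combined
    1H/15N amide shifts, one-site isothermal titration calorimetry (ITC) fitting
    with the c-value reliability rule, steady-state heteronuclear NOE rigidity
    classification, a residue-level recognition-rules engine that scores
    N-terminal/C-terminal DD pairs from their beta-strand registers and proposes
    reprogramming mutations, coordinate-level verification of interface salt
    bridges and beta-sheet registers, and synthetic-data generators with known
    ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
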