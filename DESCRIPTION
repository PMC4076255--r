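Package: glycolam
Title: Trajectory Analysis of Anhydrous Glycolipid Lamellar Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of molecular-dynamics trajectories of dry (anhydrous)
    glycolipid lamellar phases. Computes area per lipid, block-averaged local
    density profiles with lamellar d-spacing extraction, radial distribution
    functions of chain carbons under periodic boundaries, per-dihedral
    gauche/trans populations resolved by leaflet, chain-tilt distributions
    with protruding-lipid classification, and second-rank (P2) reorientational
    autocorrelation functions with single-exponential correlation times for
    C-H and sugar-ring vectors. Includes readers and writers for multi-model
    PDB and extended XYZ trajectories, a human-editable atom-role map, and a
    synthetic lamellar-trajectory generator that provides exact ground truth
    for validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
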