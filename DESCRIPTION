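Package: ligmaps
Title: Ligand-Based Virtual Screening with Ligand-Derived Grid Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ligand-based virtual screening in which one or more reference
    ligands in their bioactive conformations are turned into volumetric grid
    maps: per-atom-type pseudopotential affinity maps built from 1.54 Angstrom
    pseudospheres around each grid point, plus a distance-dependent
    electrostatic potential map. Conformationally flexible library compounds
    are scored against the maps by trilinear interpolation and optimized with
    a Lamarckian genetic algorithm over translation, rigid rotation and
    torsion genes. Raw best-pose scores are normalized by the reference
    self-score into a similarity in [0, 1], and ranked screens are evaluated
    with AUROC and enrichment factors. Reads SDF libraries and reads/writes
    PDBQT ligands and AutoDock-dialect grid map files; ligand preparation
    (Gasteiger charges, AutoDock atom types, nonpolar hydrogen merging)
    delegates to Open Babel.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
SystemRequirements: Open Babel (obabel on the PATH) for ligand preparation
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
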