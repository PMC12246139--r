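Package: bindmode
Title: Binding-Mode Analysis of Protein-Ligand Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives putative small-molecule binding modes from molecular dynamics
    trajectories of protein-ligand-solvent systems. Detects protein-ligand
    interactions (hydrogen bonds, water bridges, pi-pi and pi-cation stacking,
    hydrophobic and ionic contacts) frame by frame under explicit geometric
    criteria and aggregates them into per-residue interaction fractions across
    replicas; quantifies conserved-water-site occupancy, water exchange and
    occupancy conditioned on side-chain conformational state; classifies
    side-chain flip states from distance-angle descriptors; and selects a
    representative binding-mode frame by affinity-propagation clustering of a
    key-residue RMSD matrix. Includes a synthetic-trajectory generator that
    plants ledgered ground truth for every analysis stage, and a
    configuration-driven end-to-end pipeline with tabular and JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
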