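Package: dimerdyn
Title: Trajectory Analysis of Dimer-Interface Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify the dissociation tendency of protein homodimers
    from molecular-dynamics coordinate ensembles. Detects the subunit interface
    by solvent-accessible surface area (SASA) loss on the static structure,
    computes Shrake-Rupley SASA with deterministic sphere points, performs
    principal component analysis of alpha-carbon motions and partial-least-squares
    functional mode analysis against the interface-SASA series, compares
    per-residue mode amplitudes and directions, builds dynamic residue-interaction
    networks from joint motion-direction and contact-occupancy criteria with
    bootstrap robustness and shortest-path analysis, selects key residues from
    per-residue binding-free-energy decompositions, and clusters conformers by
    pairwise RMSD. A seeded synthetic dimer-ensemble generator with planted
    collective modes makes every stage testable without simulation output.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
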