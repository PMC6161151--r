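Package: asdstab
Title: Stability Descriptors for Amorphous Solid Dispersions from
    Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of molecular dynamics trajectories of drug-polymer
    blends to rank the physical stability of amorphous solid dispersions
    (ASDs).  Computes thermodynamic descriptors (intermolecular Coulomb
    mixing energies via an exact charge-zeroing decomposition, with
    direct, minimum-image and Ewald electrostatics; hydrogen-bond count
    changes upon mixing) and kinetic descriptors (translational diffusion
    coefficients from mean-squared displacements, roto-vibrational
    fluctuations from per-molecule RMSF), aggregates replicate
    simulations, and correlates descriptor tables with experimental
    amorphicity indices to classify whether thermodynamics or kinetics
    limits stability.  Includes readers and writers for GRO/PDB/XYZ
    structures and multi-frame trajectories, a YAML topology format, and
    synthetic-trajectory generators (Brownian, harmonic, hydrogen-bond
    and charged-lattice fixtures) so every stage is testable without an
    MD engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    igraph,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
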