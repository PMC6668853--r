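Package: stepfold
Title: Event-Driven Molecular Dynamics over Step Potentials with
    Replica Exchange, WHAM Melting Analysis and Rotamer-Based Stability
    Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for studying how a non-canonical amino
    acid substitution destabilizes a protein. Provides an event-driven
    discrete molecular dynamics (DMD) engine over square-well (step)
    potentials, Go-model construction from native contacts, temperature
    replica exchange with Metropolis swaps, weighted histogram analysis
    (WHAM) of melting thermodynamics and specific heat, trajectory
    analytics (RMSD superposition, RMSF, correlated-motion maps), a
    backbone-dependent rotamer-library builder for non-canonical
    residues such as beta-methylamino-L-alanine (BMAA), and a
    repacking-Monte-Carlo folding free-energy-change (ddG) scanner.
    Synthetic generators produce analytic two-state systems and
    foldable Go-model peptides so the whole pipeline runs without
    external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    yaml,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
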