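Package: solvdecomp
Title: Decompositions of Solvation Free Energies by Thermodynamic
    Integration and Mutual Information Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes and compares two decompositions of the solvation free
    energy: the canonical Ben-Naim / Yu-Karplus split into solute-solvent and
    solvent-solvent internal-energy and entropy terms, obtained by
    thermodynamic integration over a coupling parameter, and the mutual
    information expansion (MIE) of the solvent entropy into single-body terms
    and pair/triple correlation terms.  Two model systems are provided: an
    exactly enumerable 4x4 periodic Ising solvation model with a field-coupled
    central solvation shell, and a reduced-scale Lennard-Jones fluid with an
    immobilized solute sampled by Metropolis Monte Carlo.  Includes a
    Kozachenko-Leonenko k-nearest-neighbour differential entropy estimator,
    permutation reduction of identical-particle trajectories by optimal linear
    assignment, and XYZ/GRO trajectory I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
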