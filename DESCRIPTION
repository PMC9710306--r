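Package: reaxplore
Title: Guided Discovery of Reaction Pathways by Imposed Activation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semi-automatic exploration of chemical reaction pathways by
    imposed activation of a single internal coordinate. A user-chosen
    activating coordinate (bond distance, angle, or dihedral) is constrained
    at out-of-equilibrium values while the orthogonal conformational space is
    explored with RMSD-biased metadynamics; relaxed scans of the coordinate
    then drive activated conformers to products. Trajectories are
    post-processed into a ranked reaction table by converting trajectory
    minima to canonical SMILES, with transition-structure guesses and
    estimated activation energies. Ships pairwise-Morse toy reactive
    potentials and brute-force grid oracles so the whole workflow runs and is
    testable without an external electronic-structure engine; an adapter can
    drive any engine that reports energies and gradients for 3-D structures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
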