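Package: fluorff
Title: Force-Field Benchmarking and Tuning for Conformational Analysis of
    Fluorinated Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking and retuning class-I molecular-mechanics
    force fields for small fluorinated molecules such as gamma-fluorohydrins.
    Provides the bonded/nonbonded energy model with analytic forces and local
    minimization; two-stage restrained electrostatic-potential (RESP) charge
    fitting with hyperbolic regularization and symmetry constraints; hybrid
    Monte Carlo and nested Markov chain Monte Carlo samplers that recover a
    target ensemble while propagating with a cheap potential; regularized
    reoptimization of bonded parameters against reference energies; rotamer
    (g+/t/g-) conformer labelling with trajectory and Boltzmann populations;
    agreement metrics (relative-energy differences, sum of absolute population
    errors, superposition RMSD); and population-weighted NMR J-coupling
    averaging with comparison statistics against experiment. A synthetic-data
    module generates surrogate reference potentials, dihedral trajectories
    with known rotamer weights, and exact point-charge ESP grids so the whole
    pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
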