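Package: nmrefine
Title: NMR Structure Refinement by Restrained Simulated Annealing in
    Torsion Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Refines NMR solution structures against experimental
    restraints. Parses XPLOR/CNS-style NOE distance and dihedral
    restraint tables, converts them to a CHARMM-style soft-asymptote
    format, evaluates a composite reduced energy (soft-core
    stereochemistry, a contact-burial solvation surrogate, NOE and
    flat-bottom dihedral restraint terms, and statistical torsion-angle
    potentials), refines structures by Metropolis Monte Carlo simulated
    annealing in torsion space under a heat/hold/cool temperature
    schedule, and evaluates the results with restraint-violation
    statistics, steric clash and Ramachandran scores, a torsion-window
    secondary-structure ratio, and Matthews-correlation comparison of
    ligand-binding residue sets. A synthetic-fixture module generates
    ideal-geometry peptides, ground-truth-derived restraints and
    perturbed starting structures so the full pipeline runs without any
    deposited data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
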