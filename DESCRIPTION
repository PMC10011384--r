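Package: hbhydro
Title: Atomistic Hydrogen-Bond Strengths and Hydration Free Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Empirical, additive model of small-molecule hydration. Computes
    per-atom hydrogen-bond donor and acceptor strengths from
    electronegativity-equilibration (EEQ) partial charges with topological
    charge-shell corrections, calibrated so that the hydrogens and oxygen of
    an MMFF94-minimised water molecule score 1.0. Sums polar, apolar
    (surface/ring/pi) and acceptor-acceptor interaction terms into a hydration
    free energy in kJ/mol. Includes water-referenced calibration, seeded
    parameter fitting with early stopping, regression and correlation metrics
    for validation and structure-activity analysis, SVG depictions of atomic
    strengths, packaged literature tables, and a synthetic-data generator for
    fitting-recovery experiments. Molecule preparation (SMILES/SDF parsing,
    hydrogen addition, fixed-seed 3D embedding, MMFF94 minimisation) is
    delegated to RDKit through the system Python interpreter.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on PATH
Config/testthat/edition: 3
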