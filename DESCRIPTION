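Package: nmrcsp
Title: NMR Crystallography Scoring of Crystal Structure Prediction Candidates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for selecting crystal-structure-prediction (CSP) candidates
    against solid-state NMR data. Converts per-nucleus isotropic magnetic
    shieldings (static structures or MD-frame ensembles) into chemical shifts
    by slope-constrained referencing, averages methyl protons and motional
    ensembles, scores candidates by per-element RMSD against experimental
    shift assignments, applies benchmark-window pre-filtering and
    shortlisting, compares structures by rigid-overlay RMSCD with periodic
    unwrapping, flags in-run phase transitions, and summarises lattice-energy
    landscapes. A synthetic-data module generates complete test campaigns
    (candidate packings, forward-model shieldings, assignments, jitter and
    methyl-rotor trajectories) so the whole pipeline runs without external
    electronic-structure or MD engines.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
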