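Package: dockjury
Title: Consensus (Jury) Quality Assessment of Protein-Complex Docking Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reference-free quality assessment for pools of docked
    protein-complex models. Detects inter-chain interface residues,
    computes per-residue interface-accuracy (ModFOLDIA) scores from
    minimum inter-chain heavy-atom distances, scores every model against
    every other model with the QS-score and DockQ similarity metrics to
    form QSscoreJury and DockQJury consensus scores, ingests external
    per-chain-pair scores, and aggregates everything into a single
    ModFOLDdock-style global score used to rank the pool. Includes a
    seeded rigid-body decoy generator for fully synthetic end-to-end
    testing, and writers for CASP-QA-style and tabular output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
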