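Package: apoescreen
Title: Ensemble-Docking Consensus Ranking and Interaction Analytics for
    ApoE4 Structure-Corrector Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analytics for virtual screening of apolipoprotein E4 (ApoE4)
    structure correctors: consensus ranking of ligands across an ensemble
    of apo/holo ApoE crystal structures (ratio of average holo-ApoE4 to
    average free-ApoE4 docking ranks), correlation diagnostics against
    censored Kd tables, enrichment metrics, combination and intersection
    of docking and shape-similarity hit lists, geometric protein-ligand
    interaction detectors (hydrogen bonds, pi-stacking, hydrophobic pocket
    occupancy), tryptophan-34 flip-in/flip-out classification from
    sidechain geometry, Kabsch superposition and trajectory RMSD series,
    and a seeded synthetic-data generator that emulates docking score
    matrices, toy pocket-ligand complexes and two-state sidechain flip
    trajectories so the whole pipeline is testable without any docking,
    shape-overlay or molecular-dynamics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
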