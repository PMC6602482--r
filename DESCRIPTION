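Package: epitope3d
Title: Spatial B-Cell Epitope Prediction for Protein and Glycoprotein Antigens
Version: 1.0.0
Authors@R:
    person("Maintainer", "epitope3d", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Per-residue conformational (spatial) B-cell epitope scoring on
    3D antigen structures. Parses PDB files, computes solvent accessibility
    with a deterministic Shrake-Rupley sampler, detects N-glycosylation
    sequons (Asn-X-Ser/Thr, X != Pro), enumerates surface residue triangles
    and glycosylation-triangle micro-environment features, profiles
    physico-chemical amino-acid indexes in concentric distance shells, and
    integrates six per-residue classifiers through small neural-network
    consolidators and a logistic regression, followed by a neighborhood
    calibration of the raw antigenicity score. Ships a full training
    pipeline, evaluation metrics (ROC AUC, balanced accuracy, FPR), a
    seeded synthetic antigen/complex generator so the whole pipeline is
    testable offline, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
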