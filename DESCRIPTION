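Package: kgs2
Title: Knowledge-Guided Rescoring of Protein-Ligand Binding Affinities
    with 3D Interaction Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Improves binding-affinity predictions of any scoring function
    by anchoring the query complex's score to a structurally similar
    reference complex with known experimental affinity. Protein-ligand
    interfaces are decomposed into four-atom interaction units, preferred
    unit geometries ("interaction patterns") are mined from a structure
    library with Gaussian mixture models, each complex is reduced to a 3D
    interaction fingerprint of typed residue/ligand-atom nodes, and
    fingerprints are compared by maximal-clique correspondence matching,
    rigid superposition and a Tanimoto similarity index. Includes
    calibration of the scoring-function slope, adjusted scoring with a
    linear-regression fallback, docking-pose re-ranking, and a synthetic
    fixture generator for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    mclust,
    stats,
    tools,
    utils
Suggests:
    ChemmineR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
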