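Package: ncidta
Title: Non-Covalent-Interaction-Guided Cross-Attention for Drug-Target
    Binding Affinity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Protein-ligand binding affinity regression with an explainable
    cross-modal attention mechanism. Protein residues attend over the set of
    chemical substructures given by a ligand's 1024-bit hashed circular
    (Morgan-type) fingerprint, augmented with a trainable pseudo-substructure
    key; a binary cross-entropy penalty on the head-averaged attention steers
    residues without non-covalent interactions (NCIs) toward the pseudo key,
    so that per-residue attention mass on real substructures can be read as an
    NCI probability. Includes dataset curation and affinity normalization,
    residue-wise NCI label conversion from pairwise interaction-profiler
    output, scaffold-based and k-fold splitting, a synthetic-data generator
    with planted residue-motif/substructure interaction rules, a seeded
    training engine (Adam, early stopping, fine-tuning), regression and
    explainability metrics, and attention-map export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    Rcpp,
    Biostrings,
    ChemmineOB,
    pROC
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
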