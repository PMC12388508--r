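Package: ensvar
Title: Backbone Conformational Variability of Protein Structure Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies local backbone conformational variability across an
    ensemble of X-ray structures of one protein. Chains are encoded as
    structural-letter sequences under a hidden-Markov structural alphabet
    (four-Calpha fragment geometry descriptors, Viterbi decoding), projected
    through an amino-acid multiple sequence alignment into a multiple
    structural-letter alignment, and scored per aligned position by the
    exponential of the Shannon entropy (the effective number of local
    conformations, neqSL). Companion stages normalize crystallographic
    B-factors into per-position flexibility classes, map the binding pocket by
    a superligand distance cutoff after Kabsch superposition, cluster
    co-crystallized ligands by Tanimoto similarity with Ward linkage, and
    build a bipartite residue/ligand-atom-cluster contact network filtered by
    contact recurrence. A synthetic-ensemble generator with a machine-readable
    ground-truth ledger makes every stage testable without structure
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
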