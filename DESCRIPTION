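Package: pslscreen
Title: Persistent Sheaf Laplacian Gene Ranking and CNS Drug Repurposing
Version: 0.1.0
Authors@R:
    person("pslscreen", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ranks disease-driving genes in a protein-protein interaction
    network by topological perturbation of persistent sheaf Laplacian
    spectra over a confidence filtration of clique complexes, and screens
    repurposing candidates with a dual gradient-boosted binding-affinity
    ensemble followed by CNS-oriented ADMET rules (blood-brain-barrier
    penetration and P-glycoprotein liability).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: python with rdkit (SMILES canonicalization and ECFP
    fingerprints are computed through a bundled python helper)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
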