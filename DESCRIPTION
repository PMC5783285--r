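Package: DecoyRank
Title: Ensemble Ranking-SVM Re-Ranking of Protein-Protein Docking Decoys with Schulze Consensus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Re-ranks protein-protein docking decoys by learning to rank.
    Decoys characterised by physicochemical descriptors and single-linkage
    cluster-size features are used to train an ensemble of pairwise ranking
    support vector machines on CAPRI-labelled poses. Models are selected by a
    logarithmic cluster-rank score on held-out complexes, and the selected
    ensemble's rankings are aggregated into a consensus with the Schulze
    (widest-path) electoral method. Includes training protocols with repeated
    random splits, a 50x50 regularisation/ensemble-size metaparameter grid
    with leave-one-out selection, top-k retrieval and success-rate evaluation,
    and a synthetic decoy-set generator with planted linear quality signal and
    geometrically clustered ligand poses for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    kernlab,
    bio3d,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
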