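Package: dcxnet
Title: Differential Coexpression Networks, Causal Regulators and Drug
    Connectivity Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A systems-genetics workflow for case/control transcriptome
    cohorts: robust covariate adjustment and surrogate-variable removal,
    weighted gene coexpression networks (soft-threshold adjacency,
    topological overlap, adaptive dendrogram branch cutting, module
    eigengenes, resampling robustness), modular differential connectivity
    with dual-shuffle permutation FDR, Fisher-exact enrichment and
    cross-species module conservation through many-to-many homology,
    module-trait and pathological-grade association, promoter motif
    scanning with oPOSSUM-style Z and Fisher enrichment and composite
    transcription-factor ranking, Bayesian-network ensembles with
    cis-eQTL orientation priors and h-layer key-driver calling,
    prototype-ranked-list drug connectivity scoring with permutation
    significance, and protein-interaction neighborhood enrichment.
    Includes a synthetic-study generator with planted ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
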