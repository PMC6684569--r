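Package: connAge
Title: Multi-Level Resting-State Functional Connectivity Analysis Across the Adult Lifespan
Version: 0.2.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying age-related reorganization of large-scale
    resting-state brain networks and its association with general cognitive
    performance. Implements motion screening by framewise displacement,
    nuisance (confound) regression and band-pass filtering of node time
    series, two-stage dual regression of group network templates, the
    eta-squared spatial-similarity statistic of subject network maps against
    a young-adult reference, threshold-swept graph-theoretic metrics of
    whole-brain binary networks, within- and between-network functional
    connectivity summaries on Fisher-z connectivity matrices, partial
    correlation and false-discovery-rate inference, and bootstrap mediation
    linking age, connectivity, and cognition. A synthetic-cohort generator
    with planted age effects and a known mediation structure makes the whole
    pipeline testable end-to-end without access to raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    signal,
    RNifti,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'confounds.R'
    'dualreg.R'
    'graph-metrics.R'
    'inference.R'
    'io.R'
    'mediation.R'
    'methods.R'
    'parcellation.R'
    'network-fc.R'
    'similarity.R'
    'synth-cohort.R'
    'pipeline.R'
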