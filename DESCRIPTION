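Package: hdinet
Title: Within-Subject Hub Disruption Analysis of Wavelet-Based Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds functional brain networks from regional resting-state
    time series and quantifies longitudinal, within-subject network
    reorganization. Regional series are decomposed with the maximal overlap
    discrete wavelet transform and interregional correlation matrices are
    estimated per frequency scale; graphs are binarized at fixed edge
    budgets with minimum-spanning-tree anchoring so every network stays
    connected. Nodal (degree centrality, clustering, closeness) and global
    (efficiency, path length, modularity, between-community distance)
    metrics feed a within-subject Hub Disruption Index: the regression
    slope kappa of per-node metric change against the same subject's
    reference-condition metric. Three permutation schemes (node-label
    shuffles, subject-pairing breaks, within-subject condition swaps)
    validate the index, and a covariate-constrained ISOMAP-style embedding
    ties its first coordinate to kappa for group separation testing. A
    synthetic multi-subject, multi-condition cohort generator with
    implanted, recoverable hub disruption supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
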