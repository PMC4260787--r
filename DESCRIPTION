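Package: mimenet
Title: Directed Causal Networks from Multichannel Time Series via Mixed-Embedding Mutual Information
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers directed information flow between channels of synchronized
    multichannel recordings (such as EEG) using the MIME causality measure:
    a non-uniform mixed state-space embedding is selected greedily by
    conditional mutual information (estimated with k-nearest-neighbour
    statistics), and the causal index is the share of information about the
    target's future contributed by the driver's selected lags. On top of the
    measure the package provides moving-window causality matrices, intra-brain
    and condition-contrast network construction with the radius thresholding
    rule, degree-centrality contrasts, cross-brain (hyperscanning) weight
    series and dominance links, threshold-robustness sweeps, and seeded
    synthetic-data generators with known coupling ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
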