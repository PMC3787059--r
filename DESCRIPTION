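Package: spikeCircuits
Title: Functional Networks and Circuit Groups from Multi-Neuron Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-trial weighted neuronal functional networks from
    trial-segmented spike trains (positive Pearson correlation of binned
    spike counts), partitions each network into local neuronal circuit
    groups by maximizing Newman's weighted modularity over hierarchical
    clustering cuts, clusters trials without supervision by spectral
    methods (NJW and normalized cut) on a Gaussian-kernel network
    similarity, and predicts single-trial behavioral outcomes with
    pattern-matching and k-nearest-neighbor classifiers under
    leave-one-out cross-validation. Includes a seeded simulator of
    correlated multi-neuron spike trains with trial-type-dependent
    modular structure and a matched null mode.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'synth.R'
    'io.R'
    'wnfn.R'
    'lncg.R'
    'trialCluster.R'
    'decode.R'
    'pipeline.R'
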