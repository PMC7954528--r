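Package: synarbor
Title: Linking Synapse Positions on a Neuronal Arbor to Presynaptic Functional Activity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating the anatomy of a traced postsynaptic neuron
    (synapse positions along its neurites) to the functional activity of its
    presynaptic partners recorded optically. Implements along-neurite path
    metrics on SWC skeletons, constrained single-linkage clustering of
    synapses under the tree metric, multitaper spectral coherence of
    voltage-dye traces against a reference cell, a complex-coherence
    analysis-of-variance F-ratio with permutation null, parameter sweeps over
    the clustering parameter space with Gaussian peak localization, and a
    synthetic-data generator with known ground truth for validating the
    pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    minpack.lm,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'synarbor-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'coherence.R'
    'cohstats.R'
    'skeleton.R'
    'clustering.R'
    'sweep.R'
    'synth.R'
    'io.R'
    'cli.R'
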