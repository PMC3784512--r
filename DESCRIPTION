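Package: dyncore
Title: Dynamic Community Structure and Core-Periphery Organization of
    Multilayer Functional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds multilayer functional networks from windowed
    multichannel time series via maximal-overlap discrete wavelet
    decomposition and band-averaged magnitude-squared coherence, detects
    time-evolving communities by multilayer modularity maximization with
    a Louvain-like greedy optimizer, quantifies node flexibility,
    classifies a temporal core, bulk and periphery against an
    inter-layer rewiring null model, computes continuous geometrical
    core scores by simulated annealing over ordered transition vectors,
    fits robust exponential learning curves to movement-time data, and
    links flexibility-distribution moments to learning rate.  Includes
    a synthetic-data generator with planted community dynamics,
    core-periphery contrast and behavioral ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
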