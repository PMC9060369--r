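Package: deepgate
Title: Deep Classification, Feedback Calibration and Density Clustering for
    Mass-Cytometry Cell-Type Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tri-layer workflow for single-cell mass-cytometry (CyTOF)
    data: a feedforward softmax neural network classifies cells into
    manually gated canonical populations; low-confidence cells are
    filtered into an unknown pool by per-population posterior thresholds;
    an iterative Spearman-correlation feedback loop reallocates filtered
    cells back to canonical populations; the residual unknown pool is
    embedded with a fuzzy k-nearest-neighbour manifold method and novel
    populations are extracted by hierarchical density clustering with
    condensed-tree stability selection.  Includes a synthetic CyTOF-like
    data generator, a full external-evaluation metric suite (weighted
    F-score, adjusted Rand index, Fowlkes-Mallows index, V-measure,
    neighbourhood proportion error, residual variance, ROC curve area)
    and 3-D visualisation exports with a categorical label axis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    FNN,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    uwot
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
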