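Package: profcor
Title: Phylogenetic Profiling with Distance Correlation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds phylogenetic profiles from sequence-alignment E-values,
    scores all-vs-all profile similarity with distance correlation (alongside
    Pearson correlation and mutual information over fixed-width probability
    bins), assembles pathway-graph gold standards for protein-protein
    interaction benchmarks, and evaluates predictions with binned ROC curves
    and ten-fold cross-validation. A blocked split-apply-combine engine with
    an on-disk repository of centered distance matrices keeps the all-pairs
    distance-correlation computation within bounded memory, and a synthetic
    data generator with planted dependent profile pairs makes the whole
    pipeline testable without any external database.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    parallel,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
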