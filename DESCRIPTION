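Package: strsa
Title: Spatiotemporal Representational Similarity Encoding Analysis for EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-resolved representational similarity encoding analysis
    relating layered feature-bank category geometry to per-electrode
    event-related-potential (ERP) category geometry. Provides epoch
    preprocessing (band-pass filtering, artifact rejection, baseline
    correction, sub-average bootstrapping), representational dissimilarity
    matrices (1 - Spearman) from feature banks and sliding ERP windows,
    ordinary-least-squares and single-predictor encoding with permutation
    cluster-extent correction, leave-one-participant-out noise ceilings,
    data-driven scalp electrode clustering, cross-validated linear SVM
    layer decoding, and a synthetic-data generator with planted,
    recoverable layer-to-latency-to-scalp-region structure for end-to-end
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    data.table,
    signal,
    e1071,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
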