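Package: pentropy
Title: Permutation Entropy for Short Gene-Expression Time Series
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the temporal complexity of short (as few as seven
    time points), noisy, non-equidistantly sampled gene-expression profiles
    with a modified permutation entropy built on thresholded three-point
    ordinal patterns. A "no-change" relation for expression differences below
    a replicate-derived noise threshold extends the six strict rank orderings
    of three points to the thirteen weak orderings, so that measurement noise
    does not inflate apparent complexity. Ships preprocessing (replicate
    noise-threshold estimation, low-expression filtering, cubic-spline
    resampling to an even time grid), nonparametric condition comparisons,
    gene-category enrichment, mean-entropy biclustering, correlation-network
    connectivity-degree analysis, a synthetic-data generator with controlled
    ordinal-pattern composition, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
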