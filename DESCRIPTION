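Package: bmhnet
Title: Blurred Magnitude Homology Features and Classification for Directed Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds directed functional connectomes from regional time series
    via lagged Pearson correlation, converts them to quasimetric spaces with a
    dissimilarity transform and shortest-path closure, computes blurred
    magnitude homology Betti curves (degrees 0 and 1) of weighted digraphs by
    exact boundary-operator rank computation, assembles per-subnetwork Betti
    curve feature representations, and trains a two-backbone neural network
    classifier on the joint connectome and Betti-curve features. Includes
    gradient-based subnetwork importance, per-threshold group comparison of
    Betti curves with Holm correction, and seeded generators for
    vector-autoregressive benchmark cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
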