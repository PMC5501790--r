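Package: NetScaffold
Title: Percolation and Spanning-Forest Scaffold Analysis of Functional
    Connectivity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts the basal scaffold of weighted correlation networks,
    as used in resting-state functional connectivity studies. Builds
    per-subject Pearson correlation matrices from region-of-interest time
    series, Fisher-averages them into a group matrix, runs a
    component-tracking percolation analysis with plateau statistics,
    calibrates plateau significance against an ensemble of random
    correlation matrices that preserve the observed eigenvalue spectrum
    (random orthogonal similarity plus Givens rotations), and derives the
    directed Maximum Spanning Forest and the Maximum Spanning Tree that
    distinguish chain-like from star-like network organization. Includes a
    synthetic cohort generator with planted modular structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
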