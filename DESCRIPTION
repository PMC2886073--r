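Package: raopart
Title: Partitioning Trait Diversity Among the Nodes of a Phylogeny
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes the diversity (Rao quadratic entropy) of a
    quantitative trait among the internal nodes of a rooted,
    branch-length-free phylogeny, treating replicate within-species
    measurements as virtual sister-taxa grafted below an artificial node.
    Provides the S_c trait-conservation permutation test (is intra-specific
    variability lower than inter-specific variability?), the S_3
    skewness-to-root permutation test (is diversity concentrated at
    root-ward nodes?), Abouheif's C_mean phylogenetic-signal test, and
    Hochberg's step-up multiple-testing correction, together with a
    synthetic-data generator with a controllable within-species variance
    share and a command-line pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
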