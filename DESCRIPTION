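Package: nichescape
Title: Multidimensional Niche Spaces from Mixed Trait Data, with
    Phylogenetic Comparative Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a multidimensional niche space from mixed
    (quantitative and categorical) species trait tables via factor
    analysis of mixed data, computes per-species niche uniqueness
    (mean distance to nearest neighbours) and specialisation (distance
    to the space centroid), estimates phylogenetic signal (Pagel's
    lambda) and fits Brownian-motion, Ornstein-Uhlenbeck and
    early-burst models of trait evolution with AICc model selection
    across a sample of phylogenies, and runs tree-replicated
    phylogenetic generalized least squares to identify niche elements
    associated with interspecific competition. Includes a synthetic
    data generator that simulates trees and trait tables with known
    evolutionary and regression parameters for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    nlme,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
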