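Package: mobulidID
Title: Molecular and Morphological Identification of Traded Mobulid Gill Rakers
Version: 0.1.0
Authors@R:
    person("Morgan", "Reeve", email = "mreeve.dev@posteo.net", role = c("aut", "cre"))
Description: Tools for identifying dried gill rakers of devil rays (Mobula)
    and manta rays (Manta) from market surveys. Implements DNA barcoding with
    Kimura 2-parameter distances, neighbor-joining trees with bootstrap
    support, monophyletic cluster extraction, identity-based species
    assignment and barcoding-gap summaries over COI and NADH2 markers;
    morphological trait coding with a three-step enforcement decision rule, a
    transparent naive-Bayes trait classifier and a bagged-tree ensemble with
    out-of-bag error estimation; a seeded synthetic market-survey generator;
    and market composition and price reporting with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    truncnorm,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
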