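Package: attcqtl
Title: QTL Mapping with Digenic Epistasis in Augmented Triple Test Cross Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, genome scanning and genetic-effect dissection for the
    augmented triple test cross (aTTC) mating design with a recombinant inbred
    line base population. Families obtained by crossing each line to both
    parents (L1, L2) and selfing (L4) are combined into the transformations
    Z1 = L1 + L2, Z2 = L1 - L2 and Z4 = L1 + L2 - L4, whose expectations under
    the F-infinity metric isolate augmented additive, dominance and digenic
    epistatic effects. Oversaturated genome-wide models (all marker main
    effects plus all pairwise interactions) are fitted with an empirical Bayes
    LASSO scan followed by a likelihood-ratio refit, and the augmented
    estimates are dissected algebraically into additive, dominance and all
    four digenic epistatic components, with dominance-degree classification.
    Includes a Monte Carlo study harness for power and parameter-recovery
    experiments and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    glmnet,
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
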