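Package: emmr
Title: Extended Metabolic Models from Enzyme Promiscuity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds extended metabolic models by predicting reactions that
    arise from promiscuous enzyme activity. Reaction-centre/difference/matched
    (RDM) biotransformation operators are extracted from the reactant-product
    pairs of a genome-scale metabolic model, applied to model metabolites to
    enumerate putative derivative products, reconciled against a metabolomics
    table by cross-reference majority vote, completed into atom-balanced
    stoichiometric reactions using template cofactor couples, and classified
    into four evidence categories with a decision tree. Includes a synthetic
    test-universe generator with planted promiscuous activity and a
    hand-transcribed 23-reaction curated example set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    igraph,
    ChemmineR,
    ChemmineOB,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
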