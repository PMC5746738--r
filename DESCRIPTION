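Package: mma
Title: Metabolomic Modularity Analysis of Reaction-Centric Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions a genome-scale metabolic network, represented as a
    reaction-centric graph whose edges are weighted by the density of
    statistically significant metabolites (SSMs), into a hierarchy of
    reaction modules using Newman's leading-eigenvector binary partition.
    Includes rank-sum SSM calling from replicate metabolomics peak areas
    with compartment expansion, a random connected-subgraph null model for
    empirical module probabilities, pathway-enrichment comparison to flag
    modules that span canonical pathways, and cross-condition module
    conservation. Ships a deterministic synthetic-data generator so the
    full workflow is testable without external model downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    xml2,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
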