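Package: erosionet
Title: Soil Microbiome Co-Occurrence Networks and Multifunctionality Along
    Erosion Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline linking soil erosion intensity to soil
    microbiome structure and function. Computes a soil multifunctionality
    index from standardized soil properties, alpha and beta diversity of
    OTU count tables (Shannon, observed species, ACE richness, Bray-Curtis,
    ANOSIM, constrained principal coordinate analysis), per-site Spearman
    co-occurrence networks with random-matrix-theory threshold selection
    and Benjamini-Hochberg edge filtering, global and per-sample network
    topology, keystone-taxon classification, and the statistical layer
    relating multifunctionality to diversity and network complexity.
    Includes a synthetic-data generator that emulates a two-site,
    four-erosion-level field design so the full pipeline is testable
    without sequencing data.
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
    vegan,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
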