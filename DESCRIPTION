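Package: zooarchnet
Title: Network Analysis of Zooarchaeological Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds two-mode and one-mode network graphs from taxon-by-context
    Minimum Number of Individuals (MNI) matrices, the abundance tables that
    zooarchaeologists compile for excavated contexts. Provides percent-MNI,
    Shannon diversity, richness and ubiquity metrics; habitat-based filtering
    and collapsing of invertebrate assemblages; Jaccard and Renkonen
    (percentage) similarity with strict tie thresholds and
    connectivity-preserving threshold selection; a from-scratch Girvan-Newman
    community-detection implementation with modularity-based partition
    selection; end-to-end stratigraphic and site-wide pipelines; and a
    synthetic planted-partition assemblage generator for validating group
    recovery. Ships a transcription of the published species-by-context MNI
    table for the Pineland Site Complex (southwestern Florida) as an example
    dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mclust,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
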