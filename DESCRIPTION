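Package: floodmicro
Title: Community Assembly, Multifunctionality and Co-Occurrence Networks for
    Soil Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream community-ecology analyses for multi-kingdom soil
    microbiome surveys under factorial field designs: averaged ecosystem
    multifunctionality from min-max standardized function matrices; alpha and
    beta diversity (observed richness, Shannon, Faith's phylogenetic
    diversity, Bray-Curtis) with one-factor PERMANOVA and Mantel permutation
    tests; phylogenetic and taxonomic null models of community assembly
    (beta-MNTD, beta-NTI, Raup-Crick with Bray-Curtis) with the five-process
    classification of pairwise turnover; SparCC compositional correlation
    networks with bootstrap pseudo p-values, greedy modularity, within-module
    degree / participation-coefficient node roles, and natural-connectivity
    robustness under random node removal. A synthetic-data module generates
    factorial designs, Yule phylogenies, niche-filtered or neutral ASV
    tables, seasonal function matrices and count tables with planted
    log-scale correlations so that every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    igraph,
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    picante,
    biomformat,
    pracma,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
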