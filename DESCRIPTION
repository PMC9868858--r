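Package: roadbeta
Title: Three-Facet Beta-Diversity Partitioning for Paired Road-Disturbance
    Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify biotic homogenization in paired
    roadside/interior vegetation surveys across three facets of beta
    diversity. Implements the Podani-family Jaccard partition of total
    dissimilarity into replacement and richness-difference components for
    species sets (taxonomic), functional-dendrogram branch sets
    (functional) and phylogenetic-tree branch sets (tip-weighted
    phylogenetic), plus basal-weighted phylogenetic beta diversity as
    between-community mean pairwise distance. Includes Gower distances
    over mixed trait tables, UPGMA functional dendrograms,
    correlation-based variable pruning, seeded permutation statistics
    (Mantel tests, Blomberg's K, paired sign-flip tests), a synthetic-data
    generator that emulates a paired roadside/interior design under
    environmental filtering, and a pipeline that assembles the full
    analysis into tidy result tables.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    cluster,
    jsonlite,
    optparse,
    phytools,
    picante,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
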