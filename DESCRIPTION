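Package: synmapr
Title: Comparative Genetic Mapping and Synteny Inference Between
    Chromosome-Fusion Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for cross-species comparative genetic mapping between a
    12-chromosome genome (melon-like) and a 7-chromosome genome
    (cucumber-like) believed to derive from it by chromosome fusion.
    Implements segregation screening, two-point recombination-fraction
    estimation by EM for F2 and selfed-RIL populations, LOD-threshold
    linkage grouping, marker ordering, Kosambi map distances,
    heterogeneity-filtered consensus-map merging, in silico PCR anchoring
    of mapped markers onto draft-genome scaffolds, transitive chromosome
    assignment, syntenic-block detection with colinearity statistics, and
    a ground-truthed simulator of rearranged genomes, marker panels and
    F2/RIL meioses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    igraph,
    methods,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
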