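Package: codonclust
Title: Two-Cluster Structure of Coding Genes from Second-Codon-Position
    Base Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Partitions the protein-coding genes of a genome by the
    frequencies of bases A and T at the second codon position, selects the
    optimal number of K-means clusters by mean silhouette coefficient over
    K = 2-9, and quantifies how COG functional categories are distributed
    between the resulting small and large clusters (2 x 26 chi-squared
    test plus per-category overrepresentation indicators). Cohort-level
    helpers aggregate per-genome verdicts into significance summaries,
    cumulative overrepresentation tallies, and per-phylum ratios with
    tie-excluded denominators. A synthetic coding-sequence generator with
    a two-component base-composition mixture and component-specific COG
    category distributions makes every stage testable without genome
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
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
    utils,
    withr
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
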