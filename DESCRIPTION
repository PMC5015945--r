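Package: lincphylo
Title: Comparative Genomics of lincRNA Emergence, Duplication, Loss and Decay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for studying the evolutionary dynamics of long
    intergenic noncoding RNA (lincRNA) loci across a dated species phylogeny.
    Implements a seeded local-alignment homology search with Karlin-Altschul
    E-values, reciprocal-best-hit and synteny verification against flanking
    protein-coding anchor genes, clustering of homologs into per-query
    families with a two-lineage conservation criterion, distance-based gene
    tree inference with bootstrap support, species-tree reconciliation with
    duplication dating, classification of missing loci as lost or decayed via
    relaxed-threshold re-search and a syntenic-linkage rule, and conservation
    correlates (transposable-element content, conserved noncoding sequences,
    expression, stress response, miRNA target potential, folding proxy).
    Ships a birth-death sequence simulator that plants known lincRNA
    evolutionary histories along a chronogram so every stage of the pipeline
    can be validated against complete ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    phangorn,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
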