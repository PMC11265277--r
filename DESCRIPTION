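Package: synscale
Title: Graph-Based Synteny Similarity and 16S Distance Matrix Augmentation for Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a synteny similarity measure for pairs of bacterial
    genomes from the relative order of orthologous genes: every ortholog is
    used in turn as a pivot to simulate genome circularity, cosine similarity
    is computed over ortholog rank vectors within each arrangement, and the
    median across arrangements yields the pairwise score. Provides
    covariance-based augmentation of 16S rRNA distance matrices with the
    synteny signal, MinHash genome sketching with Mash-style distances,
    complete-linkage clustering sweeps with silhouette and Rand evaluation,
    KNN-graph comparison (modularity, Jaccard family, DeltaCon with node and
    edge attribution, Girvan-Newman communities), functional gene cohort
    filters, and a synthetic genome-rearrangement simulator with known ground
    truth. Readers and writers for GenBank flat files, FASTA, labeled matrix
    TSV, BLAST tabular ortholog hits, and taxonomy tables are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
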