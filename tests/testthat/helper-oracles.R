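# Independent brute-force oracles. These deliberately avoid the package's
# internal code paths: rotations are explicit list operations, cosines use the
# direct formula, aggregation is spelled out.

# Brute-force synteny similarity over explicit list rotations.
oracle_synteny <- function(genes_a, genes_b, gene_a, gene_b,
                           mode = "genome-vectors", within = "mean") {
  rotate_to_front <- function(x, g) {
    i <- which(x == g)
    c(x[i:length(x)], if (i > 1) x[seq_len(i - 1)])
  }
  score_arrangement <- function(ord_a, ord_b) {
    ra <- match(gene_a, ord_a)
    rb <- match(gene_b, ord_b)
    n <- length(gene_a)
    cosines <- c()
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (mode == "genome-vectors") {
          u <- c(ra[i], ra[j]); v <- c(rb[i], rb[j])
        } else {
          u <- c(ra[i], rb[i]); v <- c(ra[j], rb[j])
        }
        cosines <- c(cosines,
                     sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2))))
      }
    }
    if (within == "mean") mean(cosines) else median(cosines)
  }
  scores <- score_arrangement(genes_a, genes_b)
  for (p in seq_along(gene_a)) {
    scores <- c(scores,
                score_arrangement(rotate_to_front(genes_a, gene_a[p]),
                                  rotate_to_front(genes_b, gene_b[p])))
  }
  list(scores = scores, similarity = median(scores))
}

# sample() treats a length-1 vector as 1:x; this always samples the set.
sample_from <- function(x, size = 1) x[sample.int(length(x), size)]

# Random small genome pair with full or partial orthology.
random_pair_fixture <- function(n_a, n_b = n_a, n_orth = 2) {
  genes_a <- paste0("a", sample(seq_len(n_a)))
  genes_b <- paste0("b", sample(seq_len(n_b)))
  ia <- sample(seq_len(n_a), n_orth)
  ib <- sample(seq_len(n_b), n_orth)
  list(order_a = gene_order("A", genes_a, 1000 * n_a),
       order_b = gene_order("B", genes_b, 1000 * n_b),
       genes_a = genes_a, genes_b = genes_b,
       gene_a = genes_a[ia], gene_b = genes_b[ib],
       orthologs = ortholog_set("A", "B", genes_a[ia], genes_b[ib]))
}

# Naive exact canonical k-mer set of a sequence (oracle for the sketch).
oracle_canonical_kmers <- function(seq, k) {
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  n <- nchar(seq)
  if (n < k) return(character())
  km <- substring(seq, seq_len(n - k + 1), k:n)
  km <- km[!grepl("N", km, fixed = TRUE)]
  unique(pmin(km, vapply(km, revcomp, character(1))))
}

# Naive agglomerative complete-linkage clustering (independent of hclust).
oracle_complete_linkage_labels <- function(d, k) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  lab <- integer(n)
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
  lab
}

# DeltaCon affinity assembled independently (edge loops + qr.solve).
oracle_deltacon_affinity <- function(g, epsilon) {
  n <- length(g$nodes)
  a <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  for (r in seq_len(nrow(g$edges))) {
    a[g$edges$u[r], g$edges$v[r]] <- 1
    a[g$edges$v[r], g$edges$u[r]] <- 1
  }
  m <- diag(n)
  for (i in seq_len(n)) m[i, i] <- 1 + epsilon^2 * sum(a[i, ])
  qr.solve(m - epsilon * a)
}

# Random symmetric distance matrix with distinct off-diagonal values.
random_distance_matrix <- function(n, labels = sprintf("s%02d", seq_len(n))) {
  v <- matrix(0, n, n)
  vals <- sample(seq_len(n * (n - 1) / 2)) / (n * (n - 1) / 2)
  v[upper.tri(v)] <- vals
  v <- v + t(v)
  dimnames(v) <- list(labels, labels)
  labeled_matrix(v, kind = "distance")
}

# Write a small synthetic two-record GenBank flat file; returns the path.
write_genbank_fixture <- function(path = tempfile(fileext = ".gbk")) {
  lines <- c(
    "LOCUS       TESTCHR              5000 bp    DNA     circular BCT 01-JAN-2024",
    "DEFINITION  Synthetic test chromosome.",
    "FEATURES             Location/Qualifiers",
    "     source          1..5000",
    "     CDS             100..1099",
    '                     /locus_tag="g1"',
    '                     /product="DNA polymerase III"',
    "     CDS             complement(1200..2199)",
    '                     /locus_tag="g2"',
    '                     /gene="abcB"',
    '                     /product="putative transposase"',
    "     rRNA            2300..3799",
    '                     /locus_tag="g3"',
    '                     /product="16S ribosomal RNA"',
    "ORIGIN",
    "//",
    "LOCUS       TESTPLS              2000 bp    DNA     circular BCT 01-JAN-2024",
    "DEFINITION  Synthetic test plasmid.",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..900",
    '                     /locus_tag="p1"',
    '                     /product="Conjugative transfer protein"',
    "//"
  )
  writeLines(lines, path)
  path
}

# One random block transposition of a gene-order vector (test-local copy so
# monotonicity checks do not depend on the simulator's internals).
transpose_once <- function(x) {
  n <- length(x)
  b <- sort(sample.int(n, 2))
  block <- x[b[1]:b[2]]
  rest <- x[-(b[1]:b[2])]
  if (length(rest) == 0) return(x)
  at <- sample.int(length(rest) + 1, 1)
  append(rest, block, after = at - 1)
}
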