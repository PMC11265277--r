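#' Synthetic corpus configuration
#'
#' Generative parameters for synthetic genome corpora with known ground
#' truth. Genomes are grouped; each group descends from its own ancestor
#' gene order, so within-group pairs share orthologs and synteny while
#' between-group pairs share none — the statistical structure the measure is
#' meant to detect (within-genus pairs carry signal, out-of-genus pairs are
#' missing).
#'
#' Defaults describe an "easy" corpus of 3 groups x 10 genomes with 30 genes
#' each, high ortholog retention (0.9), one rotation plus one transposition
#' per descendant, and 1% per-site divergence over 900 bp genes.
#'
#' @param n_genomes total genomes (split as evenly as possible over groups).
#' @param genes_per_genome genes in each ancestor (>= 3).
#' @param n_groups number of ancestral groups.
#' @param rotations,transpositions,reversals rearrangement operations applied
#'   to each descendant's circular gene order.
#' @param ortholog_retention per-gene probability that a descendant keeps an
#'   ancestor gene, independently per genome.
#' @param substitution_rate per-site substitution probability.
#' @param gene_length_bp length of every simulated gene.
#' @param seed RNG seed; corpora are fully reproducible from it.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_genomes = 30L, genes_per_genome = 30L,
                              n_groups = 3L, rotations = 1L,
                              transpositions = 1L, reversals = 0L,
                              ortholog_retention = 0.9,
                              substitution_rate = 0.01,
                              gene_length_bp = 900L, seed = 1L) {
  if (genes_per_genome < 3 && (reversals > 0 || transpositions > 0)) {
    stop("config error: rearrangements need at least 3 genes per genome")
  }
  stopifnot(n_genomes >= 2, n_groups >= 1,
            ortholog_retention > 0, ortholog_retention <= 1,
            substitution_rate >= 0, substitution_rate < 1)
  structure(list(n_genomes = as.integer(n_genomes),
                 genes_per_genome = as.integer(genes_per_genome),
                 n_groups = as.integer(n_groups),
                 rotations = as.integer(rotations),
                 transpositions = as.integer(transpositions),
                 reversals = as.integer(reversals),
                 ortholog_retention = ortholog_retention,
                 substitution_rate = substitution_rate,
                 gene_length_bp = as.integer(gene_length_bp),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# One random circular rotation of an index permutation.
apply_rotation <- function(perm) {
  n <- length(perm)
  p <- sample.int(n, 1)
  perm[((seq_len(n) + p - 2) %% n) + 1]
}

# Excise a random block and reinsert it at a random position.
apply_transposition <- function(perm) {
  n <- length(perm)
  b <- sort(sample.int(n, 2))
  block <- perm[b[1]:b[2]]
  rest <- perm[-(b[1]:b[2])]
  if (length(rest) == 0) return(perm)
  at <- sample.int(length(rest) + 1, 1)
  append(rest, block, after = at - 1)
}

# Reverse a random block in place.
apply_reversal <- function(perm) {
  n <- length(perm)
  b <- sort(sample.int(n, 2))
  perm[b[1]:b[2]] <- rev(perm[b[1]:b[2]])
  perm
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(bases, b), 1)
    }, character(1))
  }
  paste(chars, collapse = "")
}

sequence_identity_pct <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  100 * mean(ra == rb)
}

#' Simulate a synthetic genome corpus with known ground truth
#'
#' Each group gets an ancestor gene order (and, optionally, ancestor gene
#' sequences); descendants apply the configured numbers of random circular
#' rotations, block transpositions and segment reversals, retain each
#' ancestor gene independently with probability `ortholog_retention`, and
#' mutate sequences i.i.d. per site. Orthologs link the ancestor genes
#' retained by both genomes of a within-group pair; between-group pairs share
#' none.
#'
#' @param cfg a [simulation_config()].
#' @param with_sequences also simulate nucleotide sequences and per-pair
#'   identities (default `TRUE`; turn off for order-only studies).
#' @return list with `orders` (named list of [gene_order()]), `ortholog_sets`
#'   (list of [ortholog_set()], within-group pairs only), `sequences` (named
#'   list: genome -> named character vector of gene sequences, or `NULL`),
#'   `taxonomy` (data.frame `genome_id`, `group`), and `config`.
#' @export
simulate_corpus <- function(cfg = simulation_config(), with_sequences = TRUE) {
  set.seed(cfg$seed)
  ng <- cfg$genes_per_genome
  groups <- rep(seq_len(cfg$n_groups), length.out = cfg$n_genomes)
  genome_ids <- sprintf("G%d_S%02d", groups, seq_len(cfg$n_genomes))

  anc_seqs <- if (with_sequences) {
    lapply(seq_len(cfg$n_groups), function(g) {
      vapply(seq_len(ng), function(i) random_dna(cfg$gene_length_bp),
             character(1))
    })
  } else NULL

  orders <- list()
  kept_anc <- list()    # per genome: retained ancestor gene indices, in order
  seqs <- if (with_sequences) list() else NULL
  for (i in seq_along(genome_ids)) {
    id <- genome_ids[i]
    perm <- seq_len(ng)
    for (r in seq_len(cfg$rotations)) perm <- apply_rotation(perm)
    for (r in seq_len(cfg$transpositions)) perm <- apply_transposition(perm)
    for (r in seq_len(cfg$reversals)) perm <- apply_reversal(perm)
    retained <- which(stats::runif(ng) < cfg$ortholog_retention)
    if (length(retained) < 2) retained <- sort(sample.int(ng, 2))
    ordered_anc <- perm[perm %in% retained]
    gene_ids <- sprintf("%s_g%03d", id, ordered_anc)
    orders[[id]] <- gene_order(id, gene_ids,
                               genome_length_bp = length(gene_ids) *
                                 cfg$gene_length_bp)
    kept_anc[[id]] <- ordered_anc
    if (with_sequences) {
      gs <- vapply(anc_seqs[[groups[i]]][ordered_anc], mutate_sequence,
                   character(1), rate = cfg$substitution_rate)
      names(gs) <- gene_ids
      seqs[[id]] <- gs
    }
  }

  ortholog_sets <- list()
  for (a in seq_along(genome_ids)) {
    for (b in seq_along(genome_ids)) {
      if (b <= a || groups[a] != groups[b]) next
      ia <- genome_ids[a]; ib <- genome_ids[b]
      shared <- intersect(kept_anc[[ia]], kept_anc[[ib]])
      if (length(shared) < 2) next
      gene_a <- sprintf("%s_g%03d", ia, shared)
      gene_b <- sprintf("%s_g%03d", ib, shared)
      ident <- if (with_sequences) {
        vapply(seq_along(shared), function(k) {
          sequence_identity_pct(seqs[[ia]][[gene_a[k]]],
                                seqs[[ib]][[gene_b[k]]])
        }, numeric(1))
      } else NULL
      ortholog_sets[[length(ortholog_sets) + 1L]] <-
        ortholog_set(ia, ib, gene_a, gene_b, identity_pct = ident,
                     aligned_length_bp = rep(cfg$gene_length_bp,
                                             length(shared)))
    }
  }

  list(orders = orders, ortholog_sets = ortholog_sets, sequences = seqs,
       taxonomy = data.frame(genome_id = genome_ids, group = groups,
                             stringsAsFactors = FALSE),
       config = cfg)
}

#' Bundled worked examples of the synteny measure
#'
#' Two tiny genome pairs with hand-enumerable arrangement scores, used in
#' documentation and tests:
#' * `two_gene`: A = (g1, g2) against its reversal B = (h2, h1), full
#'   orthology. Per-arrangement scores `(0.8, 1, 1)`, median 1.
#' * `three_gene`: A = (g1, g2, g3) against its full reversal
#'   B = (h3, h2, h1). Per-arrangement scores
#'   `((2 * 7/sqrt(65) + 0.6) / 3, x, x, x)` with
#'   `x = (2 * 7/sqrt(50) + 12/13) / 3 ~ 0.9677`; median `x`.
#'
#' @return list of the two cases, each with `order_a`, `order_b`,
#'   `orthologs`, `expected_scores` and `expected_similarity`.
#' @export
worked_example <- function() {
  pivot_score <- (2 * 7 / sqrt(50) + 12 / 13) / 3
  list(
    two_gene = list(
      order_a = gene_order("A", c("g1", "g2"), 2000),
      order_b = gene_order("B", c("h2", "h1"), 2000),
      orthologs = ortholog_set("A", "B", c("g1", "g2"), c("h1", "h2")),
      expected_scores = c(0.8, 1, 1),
      expected_similarity = 1
    ),
    three_gene = list(
      order_a = gene_order("A", c("g1", "g2", "g3"), 3000),
      order_b = gene_order("B", c("h3", "h2", "h1"), 3000),
      orthologs = ortholog_set("A", "B", c("g1", "g2", "g3"),
                               c("h1", "h2", "h3")),
      expected_scores = c((2 * 7 / sqrt(65) + 0.6) / 3,
                          pivot_score, pivot_score, pivot_score),
      expected_similarity = pivot_score
    )
  )
}
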