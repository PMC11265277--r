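#' Orthologous gene pairs between two genomes
#'
#' The cross edges of the pair synteny graph: each row links one gene of
#' genome A to one gene of genome B. Identity and aligned length are optional
#' (they are needed for canonicalization tie-breaking and for coverage).
#'
#' @param genome_a,genome_b genome ids.
#' @param gene_a,gene_b character vectors of paired gene ids (same length).
#' @param identity_pct optional numeric vector in `[0, 100]`.
#' @param aligned_length_bp optional integer vector.
#' @return object of class `ortholog_set`.
#' @export
ortholog_set <- function(genome_a, genome_b, gene_a, gene_b,
                         identity_pct = NULL, aligned_length_bp = NULL) {
  if (length(gene_a) != length(gene_b)) {
    stop("ortholog_set: gene_a and gene_b differ in length")
  }
  pairs <- data.frame(gene_a = as.character(gene_a),
                      gene_b = as.character(gene_b),
                      stringsAsFactors = FALSE)
  if (!is.null(identity_pct)) pairs$identity_pct <- as.numeric(identity_pct)
  if (!is.null(aligned_length_bp)) {
    pairs$aligned_length_bp <- as.numeric(aligned_length_bp)
  }
  structure(list(genome_a = as.character(genome_a),
                 genome_b = as.character(genome_b),
                 pairs = pairs),
            class = "ortholog_set")
}

#' @export
print.ortholog_set <- function(x, ...) {
  cat(sprintf("<ortholog_set> %s ~ %s: %d pairs\n",
              x$genome_a, x$genome_b, nrow(x$pairs)))
  invisible(x)
}

#' Swap the two genomes of an ortholog set
#' @param os an [ortholog_set()].
#' @return the same set with A and B roles exchanged.
#' @export
swap_ortholog_set <- function(os) {
  out <- ortholog_set(os$genome_b, os$genome_a,
                      gene_a = os$pairs$gene_b, gene_b = os$pairs$gene_a,
                      identity_pct = os$pairs$identity_pct,
                      aligned_length_bp = os$pairs$aligned_length_bp)
  out
}

#' Reduce many-to-many ortholog hits to a one-to-one mapping
#'
#' Pivot arrangements need exactly one partner per gene. Hits are taken
#' greedily in order of decreasing identity, breaking ties by longer aligned
#' length and then by lexicographic gene ids; a hit is kept only if neither
#' of its genes is already matched.
#'
#' @param os an [ortholog_set()] (possibly many-to-many).
#' @return an [ortholog_set()] whose mapping is one-to-one.
#' @export
canonicalize_orthologs <- function(os) {
  p <- os$pairs
  if (nrow(p) == 0) return(os)
  ident <- if (is.null(p$identity_pct)) rep(0, nrow(p)) else p$identity_pct
  alen <- if (is.null(p$aligned_length_bp)) rep(0, nrow(p)) else p$aligned_length_bp
  ord <- order(-ident, -alen, p$gene_a, p$gene_b)
  p <- p[ord, , drop = FALSE]
  used_a <- character(); used_b <- character()
  keep <- logical(nrow(p))
  for (i in seq_len(nrow(p))) {
    if (!(p$gene_a[i] %in% used_a) && !(p$gene_b[i] %in% used_b)) {
      keep[i] <- TRUE
      used_a <- c(used_a, p$gene_a[i])
      used_b <- c(used_b, p$gene_b[i])
    }
  }
  p <- p[keep, , drop = FALSE]
  ortholog_set(os$genome_a, os$genome_b, p$gene_a, p$gene_b,
               identity_pct = p$identity_pct,
               aligned_length_bp = p$aligned_length_bp)
}

# Ranks of the ortholog genes in each genome (1-based over the full order,
# or over the orthologous genes only when rank_scope = "ortholog-genes").
ortholog_ranks <- function(order_a, order_b, os,
                           rank_scope = c("all-genes", "ortholog-genes")) {
  rank_scope <- match.arg(rank_scope)
  ra <- gene_ranks(order_a, os$pairs$gene_a)
  rb <- gene_ranks(order_b, os$pairs$gene_b)
  if (rank_scope == "ortholog-genes") {
    ra <- rank(ra); rb <- rank(rb)
    na <- length(ra); nb <- length(rb)
  } else {
    na <- length(order_a$ordered_gene_ids)
    nb <- length(order_b$ordered_gene_ids)
  }
  list(ra = as.numeric(ra), rb = as.numeric(rb), na = na, nb = nb)
}

# Circular rotation so that the gene at rank `pivot_rank` gets rank 1 and all
# other genes keep their cyclic order.
rotate_ranks <- function(r, pivot_rank, n) {
  ((r - pivot_rank) %% n) + 1
}

#' Build all arrangements of a genome pair
#'
#' The first arrangement is the original order as read from the flat files;
#' one further arrangement per ortholog pair rotates both circular gene
#' orders so that the pivot pair's genes take rank 1 in their respective
#' genomes (the remaining genes follow in cyclic order).
#'
#' @param order_a,order_b [gene_order()] objects.
#' @param orthologs an [ortholog_set()] with at least two pairs (already
#'   one-to-one; see [canonicalize_orthologs()]).
#' @param rank_scope rank genes over the full gene order (default) or over
#'   the orthologous genes only.
#' @return list of arrangements; each has `pivot` (`"original"` or the index
#'   of the pivot ortholog pair) and full rank maps `rank_a`, `rank_b`
#'   (named numeric vectors over every gene of each genome, each a
#'   permutation of `1..N`).
#' @export
build_arrangements <- function(order_a, order_b, orthologs,
                               rank_scope = c("all-genes", "ortholog-genes")) {
  rank_scope <- match.arg(rank_scope)
  n_pairs <- nrow(orthologs$pairs)
  if (n_pairs < 2) {
    stop("insufficient orthologs: at least two ortholog pairs are required (got ",
         n_pairs, ")")
  }
  if (rank_scope == "all-genes") {
    genes_a <- order_a$ordered_gene_ids
    genes_b <- order_b$ordered_gene_ids
  } else {
    rk <- ortholog_ranks(order_a, order_b, orthologs, rank_scope)
    genes_a <- orthologs$pairs$gene_a[order(rk$ra)]
    genes_b <- orthologs$pairs$gene_b[order(rk$rb)]
  }
  base_a <- stats::setNames(seq_along(genes_a), genes_a)
  base_b <- stats::setNames(seq_along(genes_b), genes_b)
  na <- length(genes_a); nb <- length(genes_b)

  arrs <- vector("list", n_pairs + 1L)
  arrs[[1]] <- list(pivot = "original", rank_a = base_a, rank_b = base_b)
  for (p in seq_len(n_pairs)) {
    pa <- base_a[[orthologs$pairs$gene_a[p]]]
    pb <- base_b[[orthologs$pairs$gene_b[p]]]
    arrs[[p + 1L]] <- list(
      pivot = p,
      rank_a = rotate_ranks(base_a, pa, na),
      rank_b = rotate_ranks(base_b, pb, nb)
    )
  }
  arrs
}

# Cosine scores for one arrangement given the ortholog rank vectors.
# Returns the vector of C(n,2) cosines (upper triangle order).
arrangement_cosines <- function(ra, rb,
                                pair_vector_mode = c("genome-vectors",
                                                     "ortholog-vectors")) {
  pair_vector_mode <- match.arg(pair_vector_mode)
  n <- length(ra)
  up <- upper.tri(matrix(0, n, n))
  if (pair_vector_mode == "genome-vectors") {
    # u = (rank_A(i), rank_A(j)), v = (rank_B(i), rank_B(j))
    pr <- ra * rb
    num <- outer(pr, pr, "+")
    den <- sqrt(outer(ra^2, ra^2, "+") * outer(rb^2, rb^2, "+"))
  } else {
    # u = (rank_A(i), rank_B(i)), v = (rank_A(j), rank_B(j))
    num <- outer(ra, ra) + outer(rb, rb)
    q <- sqrt(ra^2 + rb^2)
    den <- outer(q, q)
  }
  (num / den)[up]
}

#' Synteny score of a single arrangement
#'
#' For every unordered combination of two ortholog pairs the cosine
#' similarity of their rank vectors is computed; the scores are combined
#' with the within-arrangement statistic (mean by default).
#'
#' In the default `"genome-vectors"` mode the vectors compared are
#' `u = (rank_A(i), rank_A(j))` against `v = (rank_B(i), rank_B(j))`; the
#' alternative `"ortholog-vectors"` mode compares
#' `u = (rank_A(i), rank_B(i))` against `v = (rank_A(j), rank_B(j))`.
#'
#' @param arr one arrangement from [build_arrangements()].
#' @param orthologs the [ortholog_set()] used to build the arrangements.
#' @param pair_vector_mode `"genome-vectors"` (default) or
#'   `"ortholog-vectors"`.
#' @param within_arrangement `"mean"` (default) or `"median"`.
#' @return score in `(0, 1]` (ranks are positive, so no cosine can be 0).
#' @export
arrangement_score <- function(arr, orthologs,
                              pair_vector_mode = c("genome-vectors",
                                                   "ortholog-vectors"),
                              within_arrangement = c("mean", "median")) {
  within_arrangement <- match.arg(within_arrangement)
  ra <- unname(arr$rank_a[orthologs$pairs$gene_a])
  rb <- unname(arr$rank_b[orthologs$pairs$gene_b])
  if (anyNA(ra) || anyNA(rb)) {
    stop("arrangement_score: ortholog genes missing from arrangement ranks")
  }
  cosines <- arrangement_cosines(ra, rb, pair_vector_mode)
  switch(within_arrangement,
         mean = mean(cosines),
         median = stats::median(cosines))
}

#' Synteny similarity of a genome pair
#'
#' The full measure: build the original arrangement plus one pivot
#' arrangement per ortholog pair (simulating genome circularity), score each
#' arrangement with [arrangement_score()], and take the median across
#' arrangements (even counts use the midpoint of the central pair).
#'
#' @inheritParams build_arrangements
#' @inheritParams arrangement_score
#' @param canonicalize reduce many-to-many hits to one-to-one first
#'   (default `TRUE`).
#' @return object of class `synteny_result` with fields `similarity`,
#'   `per_arrangement_scores`, `n_arrangements`, `n_ortholog_pairs`, or an
#'   object of class `synteny_skip` when fewer than two ortholog pairs
#'   remain (the pair is skipped at matrix level).
#' @export
synteny_similarity <- function(order_a, order_b, orthologs,
                               pair_vector_mode = c("genome-vectors",
                                                    "ortholog-vectors"),
                               within_arrangement = c("mean", "median"),
                               rank_scope = c("all-genes", "ortholog-genes"),
                               canonicalize = TRUE) {
  pair_vector_mode <- match.arg(pair_vector_mode)
  within_arrangement <- match.arg(within_arrangement)
  rank_scope <- match.arg(rank_scope)
  if (canonicalize) orthologs <- canonicalize_orthologs(orthologs)
  n_pairs <- nrow(orthologs$pairs)
  if (n_pairs < 2) {
    return(structure(list(n_ortholog_pairs = n_pairs), class = "synteny_skip"))
  }

  rk <- ortholog_ranks(order_a, order_b, orthologs, rank_scope)
  scores <- numeric(n_pairs + 1L)
  # arrangement 1: original order; then one rotation per pivot pair
  pivots_a <- c(NA, rk$ra)
  pivots_b <- c(NA, rk$rb)
  for (t in seq_len(n_pairs + 1L)) {
    if (t == 1L) {
      ra <- rk$ra; rb <- rk$rb
    } else {
      ra <- rotate_ranks(rk$ra, pivots_a[t], rk$na)
      rb <- rotate_ranks(rk$rb, pivots_b[t], rk$nb)
    }
    cosines <- arrangement_cosines(ra, rb, pair_vector_mode)
    scores[t] <- switch(within_arrangement,
                        mean = mean(cosines),
                        median = stats::median(cosines))
  }
  structure(list(similarity = stats::median(scores),
                 per_arrangement_scores = scores,
                 n_arrangements = n_pairs + 1L,
                 n_ortholog_pairs = n_pairs),
            class = "synteny_result")
}

#' @export
print.synteny_result <- function(x, ...) {
  cat(sprintf("<synteny_result> similarity=%.6f (%d arrangements, %d ortholog pairs)\n",
              x$similarity, x$n_arrangements, x$n_ortholog_pairs))
  invisible(x)
}

#' Pairwise synteny similarity matrix
#'
#' @param orders named list of [gene_order()] objects (>= 2 genomes).
#' @param ortholog_sets list of [ortholog_set()] objects; pairs without a
#'   set, or with fewer than two one-to-one ortholog pairs, get entry 0
#'   (missing).
#' @inheritParams synteny_similarity
#' @return symmetric [labeled_matrix()] of kind `"similarity"` with unit
#'   diagonal and `zero_is_missing = TRUE`.
#' @export
synteny_matrix <- function(orders, ortholog_sets,
                           pair_vector_mode = c("genome-vectors",
                                                "ortholog-vectors"),
                           within_arrangement = c("mean", "median"),
                           rank_scope = c("all-genes", "ortholog-genes"),
                           canonicalize = TRUE) {
  if (length(orders) < 2) stop("need at least 2 genomes")
  ids <- vapply(orders, function(o) o$genome_id, character(1))
  names(orders) <- ids
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 1

  for (os in ortholog_sets) {
    a <- os$genome_a; b <- os$genome_b
    if (!(a %in% ids) || !(b %in% ids) || a == b) next
    res <- synteny_similarity(orders[[a]], orders[[b]], os,
                              pair_vector_mode = pair_vector_mode,
                              within_arrangement = within_arrangement,
                              rank_scope = rank_scope,
                              canonicalize = canonicalize)
    if (inherits(res, "synteny_skip")) next
    m[a, b] <- m[b, a] <- res$similarity
  }
  labeled_matrix(m, kind = "similarity", zero_is_missing = TRUE)
}

#' Synteny coverage of one genome by its shared blocks
#'
#' Asymmetric measure: the summed length of the aligned ortholog blocks of a
#' genome pair divided by the total length of the chosen genome. When the
#' block coordinates are known (via `features`), physically overlapping
#' blocks are merged and their union length used, so a genome fully tiled by
#' orthologs scores exactly 1.
#'
#' @param order [gene_order()] of the chosen genome (with
#'   `genome_length_bp`).
#' @param orthologs [ortholog_set()] carrying `aligned_length_bp`.
#' @param which `"a"` if the chosen genome is `orthologs$genome_a`, else
#'   `"b"`.
#' @param features optional data.frame with `gene_id`, `start_bp`, `end_bp`
#'   for the chosen genome; enables overlap merging.
#' @return coverage in `[0, 1]`.
#' @export
synteny_coverage <- function(order, orthologs, which = c("a", "b"),
                             features = NULL) {
  which <- match.arg(which)
  len <- order$genome_length_bp
  if (is.na(len) || len <= 0) {
    stop("domain error: genome length must be positive")
  }
  p <- orthologs$pairs
  if (nrow(p) == 0) return(0)
  if (is.null(p$aligned_length_bp)) {
    stop("orthologs carry no aligned block lengths")
  }
  genes <- if (which == "a") p$gene_a else p$gene_b
  if (is.null(features)) {
    total <- sum(p$aligned_length_bp)
  } else {
    i <- match(genes, features$gene_id)
    if (anyNA(i)) stop("genes missing from features table: ",
                       paste(genes[is.na(i)], collapse = ", "))
    start <- features$start_bp[i]
    end <- pmin(start + p$aligned_length_bp - 1, features$end_bp[i])
    total <- merged_interval_length(start, end)
  }
  min(total / len, 1)
}

# Total length of the union of 1-based inclusive intervals.
merged_interval_length <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  total <- 0; cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e + 1) {
      cur_e <- max(cur_e, end[i])
    } else {
      total <- total + (cur_e - cur_s + 1)
      cur_s <- start[i]; cur_e <- end[i]
    }
  }
  total + (cur_e - cur_s + 1)
}
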