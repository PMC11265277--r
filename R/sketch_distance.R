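#' MinHash bottom-sketch of nucleotide sequences
#'
#' Builds a bottom-s MinHash sketch over canonical k-mers (the
#' lexicographically smaller of each k-mer and its reverse complement;
#' k-mers containing N are skipped), the scheme popularised by whole-genome
#' sketching tools. A single 64-bit hash seeded by `hash_seed` is used; hash
#' values are truncated to 53 bits so they are exact doubles.
#'
#' @param sequences character vector of nucleotide sequences over A/C/G/T/N.
#' @param kmer_size k-mer length (default 21, the common whole-genome default).
#' @param sketch_size maximum sketch size s (default 1000).
#' @param hash_seed integer seed of the hash function; sketches are only
#'   comparable at equal `kmer_size` and `hash_seed`.
#' @return object of class `sketch_profile` with fields `kmer_size`,
#'   `sketch_size`, `hash_seed` and `min_hashes` (sorted ascending, distinct;
#'   length `min(sketch_size, #distinct canonical k-mers)`).
#' @export
sketch <- function(sequences, kmer_size = 21L, sketch_size = 1000L,
                   hash_seed = 42L) {
  sequences <- as.character(sequences)
  h <- .minhash_sketch_cpp(sequences, as.integer(kmer_size),
                           as.integer(sketch_size), as.numeric(hash_seed))
  if (length(h) == 0) {
    stop("empty sketch: no valid k-mers of length ", kmer_size,
         " in the input sequences")
  }
  structure(list(kmer_size = as.integer(kmer_size),
                 sketch_size = as.integer(sketch_size),
                 hash_seed = as.integer(hash_seed),
                 min_hashes = h),
            class = "sketch_profile")
}

#' @export
print.sketch_profile <- function(x, ...) {
  cat(sprintf("<sketch_profile> k=%d s=%d seed=%d |hashes|=%d\n",
              x$kmer_size, x$sketch_size, x$hash_seed, length(x$min_hashes)))
  invisible(x)
}

check_compatible_sketches <- function(a, b) {
  if (!inherits(a, "sketch_profile") || !inherits(b, "sketch_profile")) {
    stop("sketch_profile objects required")
  }
  if (a$kmer_size != b$kmer_size) {
    stop("parameter error: sketches built with different k (",
         a$kmer_size, " vs ", b$kmer_size, ")")
  }
  if (a$hash_seed != b$hash_seed) {
    stop("parameter error: sketches built with different hash seeds")
  }
  invisible(TRUE)
}

#' Jaccard index estimate from two bottom sketches
#'
#' Merged-sketch estimator: take the s smallest distinct hashes of the union
#' of both sketches (s = the sketch size, or fewer if the union is smaller)
#' and count how many occur in both sketches.
#'
#' @param a,b `sketch_profile` objects with equal k and hash seed.
#' @return estimated Jaccard index in `[0, 1]`.
#' @export
sketch_jaccard <- function(a, b) {
  check_compatible_sketches(a, b)
  s <- min(a$sketch_size, b$sketch_size)
  merged <- sort(unique(c(a$min_hashes, b$min_hashes)))
  merged <- merged[seq_len(min(s, length(merged)))]
  shared <- sum(merged %in% a$min_hashes & merged %in% b$min_hashes)
  shared / length(merged)
}

#' Mash-style mutation distance between two sketches
#'
#' `d = -(1/k) * log(2j / (1 + j))` with `j` the merged-sketch Jaccard
#' estimate. `j = 1` gives `d = 0`; `j = 0` (where the formula diverges) is
#' clamped to `d = 1`, and any `d > 1` is likewise capped so distances stay
#' in `[0, 1]`.
#'
#' @inheritParams sketch_jaccard
#' @return distance in `[0, 1]`.
#' @export
mash_distance <- function(a, b) {
  j <- sketch_jaccard(a, b)
  if (j <= 0) return(1)
  d <- -(1 / a$kmer_size) * log(2 * j / (1 + j))
  min(max(d, 0), 1)
}

#' Distance between two sets of gene sequences
#'
#' Sketch distance aggregated over all cross pairs of genes (e.g., the
#' multiple 16S copies of two genomes): each gene of set A is compared with
#' each gene of set B and the distances combined with `aggregation`.
#'
#' @param genes_a,genes_b non-empty character vectors of gene sequences.
#' @param aggregation `"mean"` (default) or `"min"` over all cross pairs.
#' @inheritParams sketch
#' @return aggregated distance in `[0, 1]`.
#' @export
gene_set_distance <- function(genes_a, genes_b,
                              aggregation = c("mean", "min"),
                              kmer_size = 21L, sketch_size = 1000L,
                              hash_seed = 42L) {
  aggregation <- match.arg(aggregation)
  if (length(genes_a) == 0 || length(genes_b) == 0) {
    stop("missing data: both gene sets must be non-empty")
  }
  sk_a <- lapply(genes_a, sketch, kmer_size = kmer_size,
                 sketch_size = sketch_size, hash_seed = hash_seed)
  sk_b <- lapply(genes_b, sketch, kmer_size = kmer_size,
                 sketch_size = sketch_size, hash_seed = hash_seed)
  d <- outer(seq_along(sk_a), seq_along(sk_b),
             Vectorize(function(i, j) mash_distance(sk_a[[i]], sk_b[[j]])))
  switch(aggregation, mean = mean(d), min = min(d))
}

#' Pairwise sketch distance matrix over genomes
#'
#' @param genomes named list: genome_id -> character vector of sequences.
#'   With `per_gene = FALSE` (whole-genome mode) all sequences of a genome
#'   feed one sketch; with `per_gene = TRUE` each sequence is sketched
#'   separately and cross-pair distances aggregated (16S gene-set mode).
#' @param per_gene logical, see above.
#' @inheritParams gene_set_distance
#' @return symmetric [labeled_matrix()] of kind `"distance"` with zero
#'   diagonal.
#' @export
sketch_distance_matrix <- function(genomes, per_gene = FALSE,
                                   aggregation = c("mean", "min"),
                                   kmer_size = 21L, sketch_size = 1000L,
                                   hash_seed = 42L) {
  aggregation <- match.arg(aggregation)
  if (length(genomes) < 2) stop("need at least 2 genomes")
  if (is.null(names(genomes))) stop("genomes must be a named list")
  ids <- names(genomes)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (per_gene) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        m[i, j] <- m[j, i] <- gene_set_distance(
          genomes[[i]], genomes[[j]], aggregation = aggregation,
          kmer_size = kmer_size, sketch_size = sketch_size,
          hash_seed = hash_seed)
      }
    }
  } else {
    sk <- lapply(genomes, sketch, kmer_size = kmer_size,
                 sketch_size = sketch_size, hash_seed = hash_seed)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        m[i, j] <- m[j, i] <- mash_distance(sk[[i]], sk[[j]])
      }
    }
  }
  labeled_matrix(m, kind = "distance")
}
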