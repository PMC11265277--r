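#' Prepare a sparse distance matrix for clustering
#'
#' Complete-linkage clustering needs a dissimilarity for every pair; missing
#' entries (zeros flagged by `zero_is_missing`) are filled with the maximal
#' distance 1 so that genomes without data end up maximally separated.
#'
#' @param d a distance-scale [labeled_matrix()].
#' @param fill value used for missing off-diagonal entries (default 1).
#' @return a dense distance [labeled_matrix()] with zero diagonal.
#' @export
fill_missing_distances <- function(d, fill = 1) {
  v <- unclass_lm(d)
  if (zero_is_missing(d)) {
    miss <- v == 0
    diag(miss) <- FALSE
    v[miss] <- fill
  }
  diag(v) <- 0
  labeled_matrix(v, labels = matrix_labels(d), kind = "distance")
}

#' Complete-linkage hierarchical cluster labels
#'
#' Agglomerative complete-linkage clustering of a precomputed distance
#' matrix, cut into a requested number of flat clusters.
#'
#' @param d symmetric distance-scale [labeled_matrix()] with zero diagonal
#'   (missing entries are filled with distance 1 first).
#' @param n_clusters requested number of flat clusters (`1..n`).
#' @return named integer vector of cluster labels, one per genome.
#' @export
hierarchical_labels <- function(d, n_clusters) {
  n <- nrow(d)
  if (n_clusters > n || n_clusters < 1) {
    stop("domain error: n_clusters must be in 1..", n)
  }
  stats::cutree(hclust_complete(d), k = n_clusters)
}

hclust_complete <- function(d) {
  dd <- fill_missing_distances(d)
  stats::hclust(stats::as.dist(unclass_lm(dd)), method = "complete")
}

#' Export the complete-linkage dendrogram as a Newick string
#' @param d distance-scale [labeled_matrix()].
#' @param path optional file to write to.
#' @return the Newick string, invisibly if written to file.
#' @export
dendrogram_newick <- function(d, path = NULL) {
  tr <- ape::as.phylo(hclust_complete(d))
  if (!is.null(path)) {
    ape::write.tree(tr, file = path)
    return(invisible(ape::write.tree(tr)))
  }
  ape::write.tree(tr)
}

#' Silhouette score of a labeling on a precomputed distance matrix
#'
#' Mean over samples of `(b - a) / max(a, b)` where `a` is the mean
#' within-cluster distance and `b` the smallest mean distance to another
#' cluster. Members of singleton clusters score 0 by convention, as do
#' samples where `max(a, b) = 0`.
#'
#' @param d symmetric distance-scale [labeled_matrix()].
#' @param labels cluster labels in matrix label order.
#' @return mean silhouette in `[-1, 1]`.
#' @export
silhouette_score <- function(d, labels) {
  v <- unclass_lm(fill_missing_distances(d))
  n <- nrow(v)
  labels <- as.integer(factor(labels))
  if (length(labels) != n) stop("labels length must match matrix size")
  k <- length(unique(labels))
  if (k < 2) stop("silhouette undefined for a single cluster")
  sizes <- tabulate(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- labels[i]
    if (sizes[ci] == 1) { s[i] <- 0; next }
    a <- sum(v[i, labels == ci]) / (sizes[ci] - 1)  # excludes d(i,i)=0
    b <- min(vapply(setdiff(unique(labels), ci), function(cj) {
      mean(v[i, labels == cj])
    }, numeric(1)))
    m <- max(a, b)
    s[i] <- if (m == 0) 0 else (b - a) / m
  }
  mean(s)
}

#' Rand index between two clusterings
#'
#' Plain (unadjusted) Rand index: the fraction of the `C(n, 2)` sample pairs
#' on which the two clusterings agree (both together or both apart).
#' Invariant to relabeling and symmetric in its arguments.
#'
#' @param labels_1,labels_2 cluster labels over the same samples.
#' @return Rand index in `[0, 1]`.
#' @export
rand_score <- function(labels_1, labels_2) {
  if (length(labels_1) != length(labels_2)) {
    stop("alignment error: labelings cover different sample sets")
  }
  n <- length(labels_1)
  if (n < 2) stop("Rand index needs at least 2 samples")
  ct <- table(labels_1, labels_2)
  sum_ct2 <- sum(choose(ct, 2))
  sum_r2 <- sum(choose(rowSums(ct), 2))
  sum_c2 <- sum(choose(colSums(ct), 2))
  total <- choose(n, 2)
  # agreements = pairs together in both + pairs apart in both
  (total + 2 * sum_ct2 - sum_r2 - sum_c2) / total
}

#' Cluster-cutoff sweep with silhouette and Rand evaluation
#'
#' Varies the number of flat clusters, recording the silhouette score of
#' each cut and (optionally) the Rand index against a reference clustering
#' of the same matrix set at the same cutoff.
#'
#' @param d distance-scale [labeled_matrix()].
#' @param reference optional: a distance [labeled_matrix()] to cluster in
#'   parallel as the reference (e.g., ANI), or a function
#'   `cutoff -> labels`, or `NULL` to skip the Rand column.
#' @param cutoffs integer cluster counts (default `1:100`, truncated to `n`).
#' @return data.frame with columns `cutoff`, `n_clusters_found`,
#'   `silhouette` (NA where undefined, i.e. outside `2..n-1`) and `rand`
#'   (NA when no reference given).
#' @export
cluster_sweep <- function(d, reference = NULL, cutoffs = 1:100) {
  n <- nrow(d)
  cutoffs <- cutoffs[cutoffs >= 1 & cutoffs <= n]
  hc <- hclust_complete(d)
  ref_fun <- if (is.null(reference)) {
    NULL
  } else if (is.function(reference)) {
    reference
  } else {
    ref_hc <- hclust_complete(reference)
    function(k) stats::cutree(ref_hc, k = k)
  }
  out <- data.frame(cutoff = cutoffs, n_clusters_found = NA_integer_,
                    silhouette = NA_real_, rand = NA_real_)
  for (r in seq_along(cutoffs)) {
    k <- cutoffs[r]
    lab <- stats::cutree(hc, k = k)
    out$n_clusters_found[r] <- length(unique(lab))
    if (k >= 2 && k <= n - 1) {
      out$silhouette[r] <- silhouette_score(d, lab)
    }
    if (!is.null(ref_fun)) {
      out$rand[r] <- rand_score(lab, ref_fun(k))
    }
  }
  out
}
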