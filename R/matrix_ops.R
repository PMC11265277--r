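#' Convert between similarity and distance scales
#'
#' `to_distance()` maps every entry `s` to `d = 1 - s` (and vice versa for
#' `to_similarity()`). The conversion is applied verbatim: entries that
#' encoded "missing" as 0 on the similarity scale become distance 1.
#'
#' @param m a [labeled_matrix()] with values in `[0, 1]`.
#' @return a [labeled_matrix()] on the other scale.
#' @export
to_distance <- function(m) {
  if (!matrix_kind(m) %in% c("similarity", "augmented")) {
    stop("to_distance expects a similarity-scale matrix, got kind '",
         matrix_kind(m), "'")
  }
  check_unit_range(m)
  labeled_matrix(1 - unclass_lm(m), kind = "distance")
}

#' @rdname to_distance
#' @export
to_similarity <- function(m) {
  if (!matrix_kind(m) %in% c("distance", "augmented")) {
    stop("to_similarity expects a distance-scale matrix, got kind '",
         matrix_kind(m), "'")
  }
  check_unit_range(m)
  labeled_matrix(1 - unclass_lm(m), kind = "similarity")
}

check_unit_range <- function(m) {
  rng <- range(m)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("domain error: values outside [0,1]: range [",
         signif(rng[1], 6), ", ", signif(rng[2], 6), "]")
  }
  invisible(TRUE)
}

#' Covariance matrix of a pairwise matrix
#'
#' Treats columns as variables and rows as observations (unbiased `n - 1`
#' denominator by default). For symmetric input the result is symmetric.
#'
#' @param m a [labeled_matrix()] with `n >= 2`.
#' @param unbiased use the `n - 1` denominator (default); `FALSE` uses `n`.
#' @return a [labeled_matrix()] of kind `"covariance"`.
#' @export
covariance_matrix <- function(m, unbiased = TRUE) {
  n <- nrow(m)
  if (n < 2) stop("dimension error: covariance needs n >= 2")
  v <- stats::cov(unclass_lm(m))
  if (!unbiased) v <- v * (n - 1) / n
  labeled_matrix(v, labels = matrix_labels(m), kind = "covariance")
}

# Min-max normalization over all entries; a constant matrix maps to zeros.
minmax_normalize <- function(v) {
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(v * 0)
  (v - lo) / (hi - lo)
}

#' Augment a 16S distance matrix with the synteny signal
#'
#' The matrix product of the 16S distance matrix and the covariance matrix of
#' the synteny distance matrix, min-max normalized over all entries to
#' `[0, 1]`. Because the product of two symmetric matrices is not symmetric
#' in general, the result is symmetrized by averaging with its transpose
#' (default on; the pre-symmetrization maximum asymmetry is recorded in the
#' `"max_asymmetry"` attribute), and the diagonal is forced to 0 last so the
#' diagonal always reads "complete similarity".
#'
#' @param d16s 16S distance [labeled_matrix()].
#' @param dsyn synteny distance [labeled_matrix()]; labels must match `d16s`
#'   exactly (reorder upstream with the same label order).
#' @param force_symmetric average with the transpose (default `TRUE`).
#' @param zero_diagonal force the diagonal to 0 (default `TRUE`).
#' @param unbiased_cov covariance denominator, see [covariance_matrix()].
#' @return a [labeled_matrix()] of kind `"augmented"` in `[0, 1]`.
#' @export
augment <- function(d16s, dsyn, force_symmetric = TRUE, zero_diagonal = TRUE,
                    unbiased_cov = TRUE) {
  stopifnot_same_labels(d16s, dsyn)
  cv <- covariance_matrix(dsyn, unbiased = unbiased_cov)
  m <- unclass_lm(d16s) %*% unclass_lm(cv)
  m <- minmax_normalize(m)
  asym <- max(abs(m - t(m)))
  if (force_symmetric) m <- (m + t(m)) / 2
  if (zero_diagonal) diag(m) <- 0
  out <- labeled_matrix(m, labels = matrix_labels(d16s), kind = "augmented")
  attr(out, "max_asymmetry") <- asym
  out
}

#' Thresholded ("Thr") sparsity reduction
#'
#' Keeps only entries whose similarity is strictly greater than the
#' threshold (default 82%, matching the reporting floor of common ANI
#' tools); all others become missing (0). Distance-scale matrices are
#' thresholded on the equivalent similarity `1 - d` and returned on their
#' original scale with removed entries set to 0.
#'
#' @param m a similarity- or distance-scale [labeled_matrix()].
#' @param threshold_pct similarity threshold in percent (default 82).
#' @return a [labeled_matrix()] with `zero_is_missing = TRUE`.
#' @export
reduce_thr <- function(m, threshold_pct = 82) {
  thr <- threshold_pct / 100
  v <- unclass_lm(m)
  s <- if (matrix_kind(m) %in% c("distance", "augmented")) 1 - v else v
  v[s <= thr] <- 0
  labeled_matrix(v, labels = matrix_labels(m), kind = matrix_kind(m),
                 zero_is_missing = TRUE)
}

#' Support-masked ("Rem") sparsity reduction
#'
#' Keeps an entry iff the corresponding entry of the reference matrix
#' (typically ANI) is non-zero; all other entries become missing (0).
#'
#' @param m a [labeled_matrix()].
#' @param reference a [labeled_matrix()] with identical labels.
#' @return a [labeled_matrix()] with `zero_is_missing = TRUE`.
#' @export
reduce_rem <- function(m, reference) {
  stopifnot_same_labels(m, reference)
  v <- unclass_lm(m)
  v[unclass_lm(reference) == 0] <- 0
  labeled_matrix(v, labels = matrix_labels(m), kind = matrix_kind(m),
                 zero_is_missing = TRUE)
}

#' Fraction of zero entries of a matrix
#' @param m a [labeled_matrix()].
#' @return sparsity in `[0, 1]` (zero entries / n^2).
#' @export
sparsity <- function(m) {
  mean(unclass_lm(m) == 0)
}
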