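#' Labeled pairwise matrix
#'
#' The universal currency between modules: a square numeric matrix whose rows
#' and columns are indexed by genome identifiers, tagged with the scale it
#' lives on (`kind`) and whether a stored zero means "no data" rather than a
#' true zero (`zero_is_missing`). Similarity, distance and augmented matrices
#' are constrained to `[0, 1]`; ANI and covariance matrices are unconstrained.
#'
#' @param values square numeric matrix (or something coercible to one).
#' @param labels character vector of unique genome ids; defaults to the
#'   rownames of `values`.
#' @param kind one of `"similarity"`, `"distance"`, `"ani"`, `"covariance"`,
#'   `"augmented"`.
#' @param zero_is_missing logical; if `TRUE`, zero entries encode absent
#'   pairs (sparse measures such as the synteny matrix).
#' @return an object of class `labeled_matrix`: a numeric matrix with
#'   `dimnames`, plus `kind` and `zero_is_missing` attributes.
#' @export
labeled_matrix <- function(values, labels = rownames(values),
                           kind = c("similarity", "distance", "ani",
                                    "covariance", "augmented"),
                           zero_is_missing = FALSE) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("labeled_matrix: values must be square, got ",
         nrow(values), "x", ncol(values))
  }
  if (is.null(labels)) {
    stop("labeled_matrix: labels are required (no rownames on values)")
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(values)) {
    stop("labeled_matrix: ", length(labels), " labels for ",
         nrow(values), " rows")
  }
  if (anyDuplicated(labels)) {
    stop("labeled_matrix: duplicated labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  storage.mode(values) <- "double"
  if (kind %in% c("similarity", "distance", "augmented")) {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
      stop("labeled_matrix: kind '", kind,
           "' requires values in [0,1]; observed range [",
           signif(rng[1], 6), ", ", signif(rng[2], 6), "]")
    }
    values[values < 0] <- 0
    values[values > 1] <- 1
  }
  dimnames(values) <- list(labels, labels)
  structure(values, kind = kind, zero_is_missing = isTRUE(zero_is_missing),
            class = c("labeled_matrix", "matrix", "array"))
}

#' @export
print.labeled_matrix <- function(x, ...) {
  cat(sprintf("<labeled_matrix> kind=%s  n=%d  zero_is_missing=%s\n",
              attr(x, "kind"), nrow(x), attr(x, "zero_is_missing")))
  print(unclass_lm(x), ...)
  invisible(x)
}

# plain matrix view (drops class + bookkeeping attributes)
unclass_lm <- function(x) {
  y <- unclass(x)
  attr(y, "kind") <- NULL
  attr(y, "zero_is_missing") <- NULL
  y
}

#' @rdname labeled_matrix
#' @param x a `labeled_matrix`.
#' @export
matrix_kind <- function(x) attr(x, "kind")

#' @rdname labeled_matrix
#' @export
matrix_labels <- function(x) rownames(x)

#' @rdname labeled_matrix
#' @export
zero_is_missing <- function(x) isTRUE(attr(x, "zero_is_missing"))

#' Check that a matrix is symmetric to a strict tolerance
#' @param x a `labeled_matrix` or numeric matrix.
#' @param tol maximum permitted |x - t(x)| entry.
#' @return `TRUE`/`FALSE`.
#' @export
is_symmetric_matrix <- function(x, tol = 1e-12) {
  m <- unclass_lm(as.matrix(x))
  max(abs(m - t(m))) <= tol
}

# Reorder both dimensions to a given label order; errors on mismatch.
align_labels <- function(x, labels) {
  if (!setequal(rownames(x), labels)) {
    stop("label mismatch: matrices do not share the same genome set")
  }
  y <- x[labels, labels, drop = FALSE]
  labeled_matrix(y, labels = labels, kind = attr(x, "kind"),
                 zero_is_missing = attr(x, "zero_is_missing"))
}

stopifnot_same_labels <- function(a, b) {
  if (!identical(rownames(a), rownames(b))) {
    stop("label mismatch: inputs must carry identical label sets in ",
         "identical order (reorder explicitly upstream)")
  }
  invisible(TRUE)
}
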