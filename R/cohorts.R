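#' Default mobile-genetic-element keyword list
#'
#' The ten product-description keywords used to flag MGE-associated genes:
#' transposase, transposon, conjugative, integrase, integron, recombinase,
#' conjugal, mobilization, recombination, plasmid.
#'
#' @return character vector of keywords.
#' @export
mge_keywords <- function() {
  c("transposase", "transposon", "conjugative", "integrase", "integron",
    "recombinase", "conjugal", "mobilization", "recombination", "plasmid")
}

#' Cohort filter specification
#'
#' Thresholds shared by the functional gene cohorts (core genes, antibiotic
#' resistance, virulence, MGE, metabolic): database-hit identity floor,
#' ortholog identity floor, and the aligned-length window.
#'
#' @param name cohort name (`"COR"`, `"ARG"`, `"VIR"`, `"MGE"`, `"MET"` or
#'   user-defined).
#' @param db_identity_threshold_pct keep database hits with identity strictly
#'   above this (default 90).
#' @param ortholog_identity_threshold_pct keep orthologs with identity
#'   strictly above this (default 95).
#' @param min_len_bp,max_len_bp inclusive aligned-length window
#'   (defaults 500 and 2500).
#' @param keywords keyword list for MGE flagging (default [mge_keywords()]).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(name = "COR",
                        db_identity_threshold_pct = 90,
                        ortholog_identity_threshold_pct = 95,
                        min_len_bp = 500L, max_len_bp = 2500L,
                        keywords = mge_keywords()) {
  stopifnot(min_len_bp <= max_len_bp,
            db_identity_threshold_pct >= 0, db_identity_threshold_pct <= 100,
            ortholog_identity_threshold_pct >= 0,
            ortholog_identity_threshold_pct <= 100)
  structure(list(name = name,
                 db_identity_threshold_pct = db_identity_threshold_pct,
                 ortholog_identity_threshold_pct = ortholog_identity_threshold_pct,
                 min_len_bp = as.integer(min_len_bp),
                 max_len_bp = as.integer(max_len_bp),
                 keywords = keywords),
            class = "cohort_spec")
}

#' Flag mobile-genetic-element genes by product description
#'
#' Case-insensitive plain substring match of the product description against
#' the keyword list (so "transposase-like" matches "transposase").
#'
#' @param features data.frame of gene features with a `product_description`
#'   column (as returned by [read_genbank_gene_order()]).
#' @param keywords keyword list (default [mge_keywords()]).
#' @return the flagged subset of `features`.
#' @export
flag_mge <- function(features, keywords = mge_keywords()) {
  desc <- tolower(features$product_description)
  hit <- Reduce(`|`, lapply(tolower(keywords), function(k) {
    grepl(k, desc, fixed = TRUE)
  }), accumulate = FALSE)
  features[hit, , drop = FALSE]
}

#' Filter database BLAST hits by identity
#'
#' Keeps hits whose percent identity is strictly above the threshold
#' (default 90), the floor applied when matching cohort sequences against
#' their source databases.
#'
#' @param hits data.frame as from [read_ortholog_hits()].
#' @param threshold_pct identity floor, strict (default 90).
#' @return filtered data.frame.
#' @export
filter_db_hits <- function(hits, threshold_pct = 90) {
  hits[hits$identity_pct > threshold_pct, , drop = FALSE]
}

#' Filter all-vs-all hits into ortholog pairs
#'
#' Keeps hits with identity strictly above the ortholog threshold (default
#' 95) and aligned length inside the inclusive window (default 500-2500 bp);
#' drops self-hits and, when a `gene_id -> genome_id` map is supplied,
#' within-genome hits.
#'
#' @param hits data.frame as from [read_ortholog_hits()].
#' @param spec a [cohort_spec()].
#' @param genome_of optional named character vector mapping gene ids to
#'   genome ids; enables the within-genome drop and the grouping of the
#'   result into per-genome-pair [ortholog_set()] fragments.
#' @return if `genome_of` is `NULL`, the filtered hits data.frame; otherwise
#'   a list of [ortholog_set()] objects, one per genome pair.
#' @export
filter_orthologs <- function(hits, spec = cohort_spec(), genome_of = NULL) {
  keep <- hits$identity_pct > spec$ortholog_identity_threshold_pct &
    hits$aligned_length_bp >= spec$min_len_bp &
    hits$aligned_length_bp <= spec$max_len_bp &
    hits$query_gene_id != hits$subject_gene_id
  out <- hits[keep, , drop = FALSE]
  if (is.null(genome_of)) return(out)

  ga <- unname(genome_of[out$query_gene_id])
  gb <- unname(genome_of[out$subject_gene_id])
  if (anyNA(ga) || anyNA(gb)) {
    stop("genome_of does not cover all gene ids in the hit table")
  }
  cross <- ga != gb
  out <- out[cross, , drop = FALSE]
  ga <- ga[cross]; gb <- gb[cross]
  # orient every hit so genome_a < genome_b, collapse reciprocal duplicates
  flip <- ga > gb
  qa <- ifelse(flip, out$subject_gene_id, out$query_gene_id)
  qb <- ifelse(flip, out$query_gene_id, out$subject_gene_id)
  a <- pmin(ga, gb); b <- pmax(ga, gb)
  df <- data.frame(genome_a = a, genome_b = b, gene_a = qa, gene_b = qb,
                   identity_pct = out$identity_pct,
                   aligned_length_bp = out$aligned_length_bp,
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df[, c("genome_a", "genome_b", "gene_a", "gene_b")]), ]
  lapply(split(df, paste(df$genome_a, df$genome_b, sep = "\r")), function(p) {
    ortholog_set(p$genome_a[1], p$genome_b[1], p$gene_a, p$gene_b,
                 identity_pct = p$identity_pct,
                 aligned_length_bp = p$aligned_length_bp)
  })
}
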