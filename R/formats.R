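#' Read gene order and features from a GenBank flat file
#'
#' Parses the FEATURES table of a GenBank flat file and returns the genome's
#' gene order (CDS and rRNA features, in order of appearance, concatenated
#' across records in file order for multi-replicon genomes), the full feature
#' table, and the subset of rRNA features annotated as 16S ribosomal RNA.
#'
#' Gene identifiers are taken from the `/locus_tag` qualifier, falling back to
#' `/gene`. Locations of the forms `a..b`, `complement(a..b)` and
#' `join(...)`/`order(...)` (reduced to their overall span) are supported.
#'
#' @param path path to a GenBank flat file with one or more records.
#' @param sixteen_s_allowlist optional character vector of gene ids to treat
#'   as confirmed 16S genes instead of the product-string match.
#' @return a list with elements `gene_order` (a [gene_order()] object),
#'   `features` (data.frame of all CDS/rRNA features) and `sixteen_s`
#'   (data.frame subset whose product contains "16S ribosomal RNA",
#'   case-insensitively, or whose gene id is in the allowlist).
#' @export
read_genbank_gene_order <- function(path, sixteen_s_allowlist = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty GenBank file: ", path)
  locus_idx <- grep("^LOCUS\\s", lines)
  if (length(locus_idx) == 0) {
    stop("GenBank format error at line 1: no LOCUS line found in ", path)
  }
  genome_id <- sub("\\..*$", "", sub("^LOCUS\\s+(\\S+).*$", "\\1", lines[locus_idx[1]]))

  total_bp <- 0L
  feats <- list()
  rec_bounds <- c(locus_idx, length(lines) + 1L)
  for (r in seq_along(locus_idx)) {
    rec <- lines[rec_bounds[r]:(rec_bounds[r + 1L] - 1L)]
    m <- regmatches(rec[1], regexec("(\\d+)\\s+bp", rec[1]))[[1]]
    if (length(m) < 2) {
      stop("GenBank format error at line ", rec_bounds[r],
           ": LOCUS line lacks a '<n> bp' length field: ", rec[1])
    }
    total_bp <- total_bp + as.integer(m[2])
    feats[[r]] <- parse_genbank_features(rec, r - 1L, rec_bounds[r])
  }
  features <- do.call(rbind, feats)
  if (is.null(features) || nrow(features) == 0) {
    stop("empty genome: no CDS or rRNA features in ", path)
  }
  features$genome_id <- genome_id
  features$feature_index <- seq_len(nrow(features)) - 1L
  if (anyDuplicated(features$gene_id)) {
    dup <- unique(features$gene_id[duplicated(features$gene_id)])
    features$gene_id <- make.unique(features$gene_id, sep = "_dup")
    warning("duplicated gene ids made unique: ", paste(dup, collapse = ", "))
  }

  is_16s <- if (!is.null(sixteen_s_allowlist)) {
    features$gene_id %in% sixteen_s_allowlist
  } else {
    features$feature_type == "rRNA" &
      grepl("16S ribosomal RNA", features$product_description,
            ignore.case = TRUE)
  }

  go <- gene_order(genome_id, features$gene_id, genome_length_bp = total_bp)
  list(gene_order = go, features = features,
       sixteen_s = features[is_16s, , drop = FALSE])
}

# Parse one record's FEATURES block into a data.frame of CDS/rRNA features.
parse_genbank_features <- function(rec, replicon_index, line_offset) {
  fstart <- grep("^FEATURES", rec)
  if (length(fstart) == 0) return(NULL)
  fend <- grep("^(ORIGIN|CONTIG|//)", rec)
  fend <- if (length(fend)) min(fend[fend > fstart[1]]) - 1L else length(rec)
  block <- rec[(fstart[1] + 1L):fend]

  # feature headers sit at column 6; qualifier/continuation lines at column 22
  hdr <- grep("^ {5}\\S", block)
  if (length(hdr) == 0) return(NULL)
  out <- list()
  bounds <- c(hdr, length(block) + 1L)
  for (i in seq_along(hdr)) {
    first <- block[hdr[i]]
    type <- sub("^\\s+(\\S+).*$", "\\1", first)
    if (!type %in% c("CDS", "rRNA")) next
    body <- block[hdr[i]:(bounds[i + 1L] - 1L)]
    loc <- sub("^\\s+\\S+\\s+", "", first)
    # location may continue onto lines before the first qualifier
    qual_start <- grep("^\\s+/", body)
    loc_extra <- setdiff(seq_along(body)[-1],
                         if (length(qual_start)) qual_start[1]:length(body) else integer())
    if (length(loc_extra)) loc <- paste0(loc, gsub("\\s", "", body[loc_extra]))
    span <- parse_genbank_location(loc)
    if (is.null(span)) {
      stop("GenBank format error at line ",
           line_offset + fstart[1] + hdr[i] - 1L,
           ": cannot parse location '", loc, "'")
    }
    q <- parse_genbank_qualifiers(body)
    gene_id <- if (!is.na(q["locus_tag"])) q[["locus_tag"]] else q[["gene"]]
    if (is.na(gene_id)) {
      stop("GenBank format error at line ",
           line_offset + fstart[1] + hdr[i] - 1L,
           ": ", type, " feature lacks /locus_tag and /gene qualifiers")
    }
    out[[length(out) + 1L]] <- data.frame(
      genome_id = NA_character_,
      replicon_index = replicon_index,
      feature_index = NA_integer_,
      gene_id = gene_id,
      gene_name = if (is.na(q["gene"])) "" else q[["gene"]],
      product_description = if (is.na(q["product"])) "" else q[["product"]],
      start_bp = span$start, end_bp = span$end,
      strand = span$strand,
      feature_type = type,
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

parse_genbank_location <- function(loc) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  pos <- regmatches(loc, gregexpr("\\d+", loc))[[1]]
  if (length(pos) < 2) return(NULL)
  pos <- as.numeric(pos)
  list(start = min(pos), end = max(pos), strand = strand)
}

parse_genbank_qualifiers <- function(body) {
  txt <- paste(gsub("^\\s+", "", body[-1]), collapse = "\n")
  keys <- c("locus_tag", "gene", "product")
  vals <- vapply(keys, function(k) {
    m <- regmatches(txt, regexec(paste0('/', k, '="([^"]*)"'), txt))[[1]]
    if (length(m) < 2) {
      m <- regmatches(txt, regexec(paste0('/', k, '=([^\n"]+)'), txt))[[1]]
    }
    if (length(m) < 2) NA_character_ else gsub("\n\\s*", " ", m[2])
  }, character(1))
  names(vals) <- keys
  vals
}

#' Ordered gene list of one genome
#'
#' @param genome_id genome identifier.
#' @param ordered_gene_ids character vector of gene ids in genomic order
#'   (rank of gene `g` is its 1-based index here).
#' @param genome_length_bp total genome length in bp.
#' @return object of class `gene_order`.
#' @export
gene_order <- function(genome_id, ordered_gene_ids, genome_length_bp = NA_integer_) {
  ordered_gene_ids <- as.character(ordered_gene_ids)
  if (anyDuplicated(ordered_gene_ids)) {
    stop("gene_order: duplicated gene ids in ", genome_id)
  }
  structure(list(genome_id = as.character(genome_id),
                 ordered_gene_ids = ordered_gene_ids,
                 genome_length_bp = as.numeric(genome_length_bp)),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf("<gene_order> %s: %d genes, %s bp\n", x$genome_id,
              length(x$ordered_gene_ids),
              format(x$genome_length_bp, big.mark = ",")))
  invisible(x)
}

#' 1-based ranks of genes within a gene order
#' @param order a [gene_order()] object.
#' @param gene_ids genes to look up (default: all).
#' @return named integer vector of ranks.
#' @export
gene_ranks <- function(order, gene_ids = order$ordered_gene_ids) {
  r <- match(gene_ids, order$ordered_gene_ids)
  if (anyNA(r)) {
    stop("gene_ranks: unknown gene ids in ", order$genome_id, ": ",
         paste(gene_ids[is.na(r)], collapse = ", "))
  }
  names(r) <- gene_ids
  r
}

#' Read a labeled pairwise matrix from TSV
#'
#' First row and first column carry the genome labels; the body is numeric
#' with "." as decimal separator.
#'
#' @param path TSV file path.
#' @param kind matrix kind, see [labeled_matrix()].
#' @param zero_is_missing passed through to [labeled_matrix()].
#' @return a [labeled_matrix()]. Asymmetric input is accepted with a warning.
#' @export
read_matrix_tsv <- function(path, kind = "distance", zero_is_missing = FALSE) {
  raw <- utils::read.delim(path, header = TRUE, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) != ncol(raw)) {
    stop("dimension error: matrix body is ", nrow(raw), "x", ncol(raw),
         " (must be square) in ", path)
  }
  for (j in seq_len(ncol(raw))) {
    v <- raw[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      stop("parse error: non-numeric cell at row ", bad, ", column ", j,
           " ('", v[bad], "') in ", path)
    }
  }
  m <- as.matrix(raw)
  if (!identical(rownames(m), colnames(m))) {
    stop("label mismatch: row and column labels differ in ", path)
  }
  x <- labeled_matrix(m, kind = kind, zero_is_missing = zero_is_missing)
  if (!is_symmetric_matrix(x, tol = 1e-9)) {
    warning("matrix read from ", path, " is not symmetric")
  }
  x
}

#' Write a labeled matrix as TSV (canonical formatting)
#'
#' Numbers are written with `%.12g`, so `read_matrix_tsv()` followed by
#' `write_matrix_tsv()` is byte-stable and lossless to 12 significant digits.
#'
#' @param x a [labeled_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  labs <- matrix_labels(x)
  body <- apply(unclass_lm(x), 1:2, function(v) sprintf("%.12g", v))
  lines <- c(paste(c("", labs), collapse = "\t"),
             vapply(seq_along(labs), function(i) {
               paste(c(labs[i], body[i, ]), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read ortholog hits in BLAST tabular (outfmt 6) column order
#'
#' Columns used: qseqid, sseqid, pident, length (the first four); any further
#' outfmt-6 columns are ignored. No identity/length filtering happens here —
#' that is the cohorts module's job.
#'
#' @param path tab-separated hit table, no header.
#' @return data.frame with columns `query_gene_id`, `subject_gene_id`,
#'   `identity_pct`, `aligned_length_bp`.
#' @export
read_ortholog_hits <- function(path) {
  if (length(readLines(path, n = 1, warn = FALSE)) == 0) return(empty_hits())
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 4) {
    stop("schema error: ortholog hit table needs >= 4 columns ",
         "(query, subject, pident, length); got ", ncol(raw), " in ", path)
  }
  pid <- suppressWarnings(as.numeric(raw[[3]]))
  len <- suppressWarnings(as.numeric(raw[[4]]))
  if (anyNA(pid) || anyNA(len)) {
    bad <- which(is.na(pid) | is.na(len))[1]
    stop("parse error: non-numeric pident/length at row ", bad, " in ", path)
  }
  if (any(pid < 0 | pid > 100)) {
    stop("parse error: pident outside [0,100] in ", path)
  }
  data.frame(query_gene_id = as.character(raw[[1]]),
             subject_gene_id = as.character(raw[[2]]),
             identity_pct = pid,
             aligned_length_bp = as.integer(len),
             stringsAsFactors = FALSE)
}

empty_hits <- function() {
  data.frame(query_gene_id = character(), subject_gene_id = character(),
             identity_pct = numeric(), aligned_length_bp = integer(),
             stringsAsFactors = FALSE)
}

#' Read / write ortholog sets as TSV
#'
#' Format: header `genome_a gene_a genome_b gene_b identity length`, one
#' ortholog pair per row.
#'
#' @param path TSV file.
#' @return for the reader, a list of [ortholog_set()] objects (one per genome
#'   pair present in the file).
#' @export
read_ortholog_sets_tsv <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("genome_a", "gene_a", "genome_b", "gene_b")
  if (!all(need %in% names(raw))) {
    stop("schema error: ortholog set TSV needs columns ",
         paste(need, collapse = ", "))
  }
  key <- paste(raw$genome_a, raw$genome_b, sep = "\r")
  lapply(split(raw, key), function(d) {
    ortholog_set(d$genome_a[1], d$genome_b[1],
                 gene_a = d$gene_a, gene_b = d$gene_b,
                 identity_pct = if ("identity" %in% names(d)) d$identity else NULL,
                 aligned_length_bp = if ("length" %in% names(d)) d$length else NULL)
  })
}

#' @rdname read_ortholog_sets_tsv
#' @param sets list of [ortholog_set()] objects.
#' @export
write_ortholog_sets_tsv <- function(sets, path) {
  rows <- lapply(sets, function(s) {
    data.frame(genome_a = s$genome_a, gene_a = s$pairs$gene_a,
               genome_b = s$genome_b, gene_b = s$pairs$gene_b,
               identity = if (is.null(s$pairs$identity_pct)) NA else s$pairs$identity_pct,
               length = if (is.null(s$pairs$aligned_length_bp)) NA else s$pairs$aligned_length_bp,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table (genome_id, phylum, class, order, family, genus)
#' @param path TSV with header.
#' @return data.frame keyed by `genome_id`.
#' @export
read_taxonomy_tsv <- function(path) {
  tx <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!"genome_id" %in% names(tx)) {
    stop("schema error: taxonomy TSV needs a genome_id column")
  }
  tx
}

#' Read / write gene orders as TSV
#'
#' Format: header `genome_id gene_id genome_length_bp`; rows of one genome
#' appear in genomic order.
#'
#' @param path TSV file.
#' @return for the reader, a named list of [gene_order()] objects.
#' @export
read_gene_orders_tsv <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("genome_id", "gene_id", "genome_length_bp")
  if (!all(need %in% names(raw))) {
    stop("schema error: gene order TSV needs columns ",
         paste(need, collapse = ", "))
  }
  ids <- unique(raw$genome_id)
  out <- lapply(ids, function(g) {
    d <- raw[raw$genome_id == g, , drop = FALSE]
    gene_order(g, d$gene_id, genome_length_bp = d$genome_length_bp[1])
  })
  stats::setNames(out, ids)
}

#' @rdname read_gene_orders_tsv
#' @param orders named list of [gene_order()] objects.
#' @export
write_gene_orders_tsv <- function(orders, path) {
  rows <- lapply(orders, function(o) {
    data.frame(genome_id = o$genome_id, gene_id = o$ordered_gene_ids,
               genome_length_bp = o$genome_length_bp,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readDNAStringSet` returning a plain named
#' character vector, the representation the sketching module consumes.
#'
#' @param path FASTA file.
#' @return named character vector of uppercase nucleotide sequences.
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' @rdname read_fasta_sequences
#' @param seqs named character vector of sequences.
#' @export
write_fasta_sequences <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
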