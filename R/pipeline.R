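#' End-to-end pipeline over a genome corpus
#'
#' Chains the modules: input (a simulated corpus or files on disk) ->
#' synteny similarity matrix -> synteny distance -> 16S-style sketch
#' distance -> covariance augmentation -> Thr/Rem reductions ->
#' cluster-cutoff sweep -> KNN graphs with DeltaCon and Girvan-Newman
#' comparison. Every artifact is written under `out_dir` together with a
#' `manifest.json` recording inputs, configuration (including every
#' convention choice in effect: vector mode, within-arrangement statistic,
#' epsilon, missing-distance fill), package version and seed. Reruns with the
#' same config and seed are bit-identical.
#'
#' @param out_dir output directory (created if absent).
#' @param sim a [simulation_config()] to generate the corpus, or `NULL` to
#'   read from files.
#' @param orders_tsv,orthologs_tsv,d16s_tsv file-input mode: gene orders,
#'   ortholog sets and a precomputed 16S distance matrix (the latter optional
#'   if `fasta` is given).
#' @param fasta optional FASTA of genome sequences (file-input mode) used to
#'   sketch the 16S-style distance when `d16s_tsv` is absent.
#' @param ani_tsv optional ANI matrix TSV; used as the Rem reference (in
#'   simulated mode the synteny support itself is used).
#' @param pair_vector_mode,within_arrangement,rank_scope synteny conventions,
#'   see [synteny_similarity()].
#' @param thr_threshold_pct Thr similarity threshold (default 82).
#' @param cutoffs cluster-cutoff sweep range.
#' @param k KNN neighborhood size.
#' @param epsilon DeltaCon coupling (default `"auto"`).
#' @param seed RNG seed (sketching hash seed is derived from it).
#' @return invisibly, a list with the main in-memory artifacts (matrices,
#'   sweep, graphs, reports) and the manifest.
#' @export
run_pipeline <- function(out_dir,
                         sim = simulation_config(),
                         orders_tsv = NULL, orthologs_tsv = NULL,
                         d16s_tsv = NULL, fasta = NULL, ani_tsv = NULL,
                         pair_vector_mode = "genome-vectors",
                         within_arrangement = "mean",
                         rank_scope = "all-genes",
                         thr_threshold_pct = 82,
                         cutoffs = 1:15, k = 5, epsilon = "auto",
                         seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)

  if (is.null(sim)) {
    for (p in c(orders_tsv, orthologs_tsv, d16s_tsv, fasta, ani_tsv)) {
      if (!is.null(p) && !file.exists(p)) {
        stop("validation error: input path does not exist: ", p)
      }
    }
    if (is.null(orders_tsv) || is.null(orthologs_tsv)) {
      stop("validation error: file-input mode needs orders_tsv and orthologs_tsv")
    }
    orders <- read_gene_orders_tsv(orders_tsv)
    ortholog_sets <- read_ortholog_sets_tsv(orthologs_tsv)
    sequences <- if (!is.null(fasta)) {
      f <- read_fasta_sequences(fasta)
      lapply(stats::setNames(nm = names(orders)), function(g) {
        f[startsWith(names(f), g)]
      })
    } else NULL
  } else {
    corpus <- simulate_corpus(sim)
    orders <- corpus$orders
    ortholog_sets <- corpus$ortholog_sets
    sequences <- corpus$sequences
    utils::write.table(corpus$taxonomy, file.path(out_dir, "taxonomy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_gene_orders_tsv(orders, file.path(out_dir, "gene_orders.tsv"))
    write_ortholog_sets_tsv(ortholog_sets,
                            file.path(out_dir, "ortholog_sets.tsv"))
  }
  labels <- names(orders)

  syn <- synteny_matrix(orders, ortholog_sets,
                        pair_vector_mode = pair_vector_mode,
                        within_arrangement = within_arrangement,
                        rank_scope = rank_scope)
  dsyn <- to_distance(syn)

  d16s <- if (!is.null(d16s_tsv)) {
    align_labels(read_matrix_tsv(d16s_tsv, kind = "distance"), labels)
  } else if (!is.null(sequences)) {
    sketch_distance_matrix(sequences[labels], per_gene = FALSE,
                           hash_seed = seed)
  } else {
    stop("validation error: need either d16s_tsv or sequences for the 16S arm")
  }

  aug <- augment(d16s, dsyn)
  rem_ref <- if (!is.null(ani_tsv)) {
    align_labels(read_matrix_tsv(ani_tsv, kind = "ani"), labels)
  } else {
    syn
  }
  thr <- reduce_thr(aug, threshold_pct = thr_threshold_pct)
  rem <- reduce_rem(aug, rem_ref)

  write_matrix_tsv(syn, file.path(out_dir, "synteny_similarity.tsv"))
  write_matrix_tsv(dsyn, file.path(out_dir, "synteny_distance.tsv"))
  write_matrix_tsv(d16s, file.path(out_dir, "d16s.tsv"))
  write_matrix_tsv(aug, file.path(out_dir, "augmented.tsv"))
  write_matrix_tsv(thr, file.path(out_dir, "thr.tsv"))
  write_matrix_tsv(rem, file.path(out_dir, "rem.tsv"))

  sweep <- cluster_sweep(aug, reference = d16s, cutoffs = cutoffs)
  utils::write.table(sweep, file.path(out_dir, "cluster_sweep.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dendrogram_newick(aug, file.path(out_dir, "dendrogram.nwk"))

  g16 <- knn_graph(d16s, k)
  gaug <- knn_graph(aug, k)
  write_graph_tsv(g16, file.path(out_dir, "knn_16s.tsv"))
  write_graph_tsv(gaug, file.path(out_dir, "knn_augmented.tsv"))
  sims <- edge_set_similarities(g16, gaug)
  dc <- deltacon(g16, gaug, epsilon = epsilon)
  gn <- girvan_newman(gaug)
  utils::write.table(
    data.frame(node = names(gn$membership), community = gn$membership),
    file.path(out_dir, "gn_communities.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  report <- c(list(jaccard = sims$jaccard,
                   weighted_jaccard = sims$weighted_jaccard,
                   dice = sims$dice,
                   deltacon_similarity = dc$similarity,
                   deltacon_distance = dc$distance,
                   deltacon_epsilon = dc$epsilon,
                   gn_modularity = gn$modularity,
                   synteny_sparsity = sparsity(syn),
                   augmented_sparsity = sparsity(aug)))
  jsonlite::write_json(report, file.path(out_dir, "graph_report.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package = "synscale",
    version = as.character(utils::packageVersion("synscale")),
    seed = seed,
    inputs = list(simulated = !is.null(sim),
                  orders_tsv = orders_tsv, orthologs_tsv = orthologs_tsv,
                  d16s_tsv = d16s_tsv, fasta = fasta, ani_tsv = ani_tsv),
    choices = list(pair_vector_mode = pair_vector_mode,
                   within_arrangement = within_arrangement,
                   rank_scope = rank_scope,
                   thr_threshold_pct = thr_threshold_pct,
                   missing_distance_fill = 1,
                   k = k, epsilon = dc$epsilon,
                   cutoffs = range(cutoffs)),
    sim = if (!is.null(sim)) unclass(sim),
    outputs = sort(unique(c(list.files(out_dir), "manifest.json")))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(synteny = syn, d16s = d16s, augmented = aug, thr = thr,
                 rem = rem, sweep = sweep, knn_16s = g16,
                 knn_augmented = gaug, deltacon = dc, girvan_newman = gn,
                 manifest = manifest))
}
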