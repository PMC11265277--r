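two_group_matrix <- function(n1 = 3, n2 = 3, within = 0.1, between = 1) {
  n <- n1 + n2
  v <- matrix(between, n, n)
  v[seq_len(n1), seq_len(n1)] <- within
  v[(n1 + 1):n, (n1 + 1):n] <- within
  diag(v) <- 0
  labs <- sprintf("s%02d", seq_len(n))
  dimnames(v) <- list(labs, labs)
  labeled_matrix(v, kind = "distance")
}

test_that("complete linkage recovers planted groups and honours trivial cuts", {
  d <- two_group_matrix()
  lab <- hierarchical_labels(d, 2)
  expect_equal(length(unique(lab)), 2)
  expect_equal(length(unique(lab[1:3])), 1)
  expect_equal(length(unique(lab[4:6])), 1)
  expect_false(lab[1] == lab[4])

  expect_equal(length(unique(hierarchical_labels(d, 1))), 1)
  expect_equal(length(unique(hierarchical_labels(d, 6))), 6)
  expect_error(hierarchical_labels(d, 7), "domain error")
})

test_that("labels agree with a naive complete-linkage oracle for n <= 7", {
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(4:7, 1)
    d <- random_distance_matrix(n)
    v <- unclass(d)[, ]
    for (k in 2:(n - 1)) {
      got <- hierarchical_labels(d, k)
      want <- oracle_complete_linkage_labels(v, k)
      # same partition up to label renaming
      expect_equal(rand_score(got, want), 1)
    }
  }
})

test_that("missing entries cluster as maximal distance 1", {
  v <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  v["a", "b"] <- v["b", "a"] <- 0.05
  d <- labeled_matrix(v, kind = "distance", zero_is_missing = TRUE)
  filled <- fill_missing_distances(d)
  expect_equal(unclass(filled)["a", "c"], 1)
  expect_equal(unclass(filled)["a", "b"], 0.05)
  expect_equal(unname(diag(filled)), c(0, 0, 0))
  lab <- hierarchical_labels(d, 2)
  expect_equal(lab[["a"]], lab[["b"]])
  expect_false(lab[["a"]] == lab[["c"]])
})

test_that("silhouette matches the hand example and an independent implementation", {
  d <- two_group_matrix(2, 2)
  expect_equal(silhouette_score(d, c(1, 1, 2, 2)), (1 - 0.1) / 1,
               tolerance = 1e-12)

  zero <- labeled_matrix(matrix(0, 4, 4,
                                dimnames = list(letters[1:4], letters[1:4])),
                         kind = "distance")
  expect_equal(silhouette_score(zero, c(1, 2, 1, 2)), 0)

  expect_error(silhouette_score(d, rep(1, 4)), "single cluster")

  set.seed(17)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    d <- random_distance_matrix(n)
    k <- sample(2:(n - 2), 1)
    lab <- sample(seq_len(k), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    sil <- cluster::silhouette(lab, stats::as.dist(unclass(d)[, ]))
    expect_equal(silhouette_score(d, lab), mean(sil[, "sil_width"]),
                 tolerance = 1e-9)
  }
})

test_that("Rand index counts pair agreements and is relabel-invariant", {
  expect_equal(rand_score(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
  expect_equal(rand_score(rep(1, 3), 1:3), 0)
  set.seed(9)
  a <- sample(1:3, 12, replace = TRUE)
  b <- sample(1:4, 12, replace = TRUE)
  expect_equal(rand_score(a, b), rand_score(b, a))
  relab <- c(3, 1, 2)[a]
  expect_equal(rand_score(a, b), rand_score(relab, b))
  # brute-force pair count on a small case
  a3 <- c(1, 1, 2, 3); b3 <- c(1, 2, 2, 3)
  agree <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    agree <- agree + ((a3[i] == a3[j]) == (b3[i] == b3[j]))
  }
  expect_equal(rand_score(a3, b3), agree / 6)
  expect_error(rand_score(1:3, 1:4), "alignment error")
})

test_that("cluster sweep evaluates every cutoff and self-reference gives Rand 1", {
  d <- two_group_matrix(4, 4)
  sw <- cluster_sweep(d, reference = d, cutoffs = 1:8)
  expect_equal(nrow(sw), 8)
  expect_true(all(sw$rand == 1))
  expect_true(is.na(sw$silhouette[1]))      # undefined at c = 1
  expect_true(is.na(sw$silhouette[8]))      # undefined at c = n
  expect_false(anyNA(sw$silhouette[2:7]))
  expect_equal(sw$silhouette[2], max(sw$silhouette, na.rm = TRUE))
})

test_that("silhouette peaks at the true group count on easy simulated corpora", {
  wins <- 0
  for (seed in 1:20) {
    corpus <- simulate_corpus(
      simulation_config(n_genomes = 12, n_groups = 3, genes_per_genome = 12,
                        rotations = 1, transpositions = 1,
                        ortholog_retention = 0.95, seed = seed),
      with_sequences = FALSE)
    dsyn <- to_distance(synteny_matrix(corpus$orders, corpus$ortholog_sets))
    sw <- cluster_sweep(dsyn, cutoffs = 2:8)
    if (sw$cutoff[which.max(sw$silhouette)] == 3) wins <- wins + 1
  }
  expect_gte(wins, 11)  # majority over 20 seeds
})

test_that("dendrograms export as readable newick", {
  d <- two_group_matrix()
  nwk <- dendrogram_newick(d)
  expect_match(nwk, "^\\(")
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, matrix_labels(d))
})
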