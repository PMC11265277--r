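test_that("pivot arrangements are circular rotations and count n + 1", {
  oa <- gene_order("A", c("g1", "g2", "g3"), 3000)
  ob <- gene_order("B", c("h1", "h2", "h3"), 3000)
  os <- ortholog_set("A", "B", c("g1", "g2", "g3"), c("h1", "h2", "h3"))
  arrs <- build_arrangements(oa, ob, os)
  expect_length(arrs, 4)

  # pivot g2: ranks g2=1, g3=2, g1=3
  a2 <- arrs[[3]]
  expect_equal(a2$rank_a[["g2"]], 1)
  expect_equal(a2$rank_a[["g3"]], 2)
  expect_equal(a2$rank_a[["g1"]], 3)
  # pivot on the first gene reproduces the original order
  expect_equal(unname(arrs[[2]]$rank_a), unname(arrs[[1]]$rank_a))
  # every arrangement is a permutation of 1..N with the pivot at rank 1
  for (arr in arrs[-1]) {
    expect_setequal(unname(arr$rank_a), 1:3)
    expect_setequal(unname(arr$rank_b), 1:3)
    p <- arr$pivot
    expect_equal(arr$rank_a[[os$pairs$gene_a[p]]], 1)
    expect_equal(arr$rank_b[[os$pairs$gene_b[p]]], 1)
  }

  expect_error(build_arrangements(oa, ob, ortholog_set("A", "B", "g1", "h1")),
               "insufficient orthologs")
})

test_that("arrangement scores match hand-computed cosines", {
  oa <- gene_order("A", c("g1", "g2"), 2000)
  ob <- gene_order("B", c("h2", "h1"), 2000)
  os <- ortholog_set("A", "B", c("g1", "g2"), c("h1", "h2"))
  arrs <- build_arrangements(oa, ob, os)
  # original: u = (1,2) vs v = (2,1) -> cosine 4/5
  expect_equal(arrangement_score(arrs[[1]], os), 0.8, tolerance = 1e-14)

  # identical ranks in both genomes score exactly 1
  ob2 <- gene_order("B", c("h1", "h2"), 2000)
  arrs2 <- build_arrangements(oa, ob2, os)
  expect_equal(arrangement_score(arrs2[[1]], os), 1, tolerance = 1e-14)
})

test_that("worked examples reproduce their enumerated scores", {
  we <- worked_example()
  for (case in we) {
    res <- synteny_similarity(case$order_a, case$order_b, case$orthologs)
    expect_equal(res$per_arrangement_scores, case$expected_scores,
                 tolerance = 1e-12)
    expect_equal(res$similarity, case$expected_similarity, tolerance = 1e-12)
    expect_equal(res$n_arrangements, res$n_ortholog_pairs + 1)
  }
  # the three-gene full reversal lands near the known value
  expect_equal(we$three_gene$expected_similarity, 0.9677, tolerance = 1e-4)
})

test_that("production measure agrees with the brute-force oracle on small pairs", {
  set.seed(202)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    fx <- random_pair_fixture(n, n, n_orth = sample_from(2:n))
    for (mode in c("genome-vectors", "ortholog-vectors")) {
      for (within in c("mean", "median")) {
        got <- synteny_similarity(fx$order_a, fx$order_b, fx$orthologs,
                                  pair_vector_mode = mode,
                                  within_arrangement = within,
                                  canonicalize = FALSE)
        want <- oracle_synteny(fx$genes_a, fx$genes_b, fx$gene_a, fx$gene_b,
                               mode = mode, within = within)
        expect_equal(got$similarity, want$similarity, tolerance = 1e-12)
        expect_equal(sort(got$per_arrangement_scores), sort(want$scores),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("similarity is symmetric under genome swap and bounded in (0, 1]", {
  set.seed(303)
  for (rep in 1:10) {
    fx <- random_pair_fixture(sample(3:8, 1), sample(3:8, 1), n_orth = 3)
    r_ab <- synteny_similarity(fx$order_a, fx$order_b, fx$orthologs)
    r_ba <- synteny_similarity(fx$order_b, fx$order_a,
                               swap_ortholog_set(fx$orthologs))
    expect_equal(r_ab$similarity, r_ba$similarity, tolerance = 1e-12)
    expect_true(all(r_ab$per_arrangement_scores > 0))
    expect_true(all(r_ab$per_arrangement_scores <= 1 + 1e-15))
  }
})

test_that("any circular rotation with full orthology scores exactly 1", {
  set.seed(404)
  genes <- paste0("g", 1:7)
  oa <- gene_order("A", genes, 7000)
  for (shift in 1:6) {
    rot <- c(genes[(shift + 1):7], genes[1:shift])
    ob <- gene_order("B", paste0("h", sub("g", "", rot)), 7000)
    os <- ortholog_set("A", "B", genes, paste0("h", 1:7))
    res <- synteny_similarity(oa, ob, os)
    expect_equal(res$similarity, 1, tolerance = 1e-12)
  }
})

test_that("genome-vector cosines are invariant to uniform rank scaling", {
  os <- ortholog_set("A", "B", c("g1", "g2", "g3"), c("h1", "h2", "h3"))
  arr <- list(pivot = "original",
              rank_a = c(g1 = 1, g2 = 2, g3 = 3),
              rank_b = c(h1 = 3, h2 = 1, h3 = 2))
  base <- arrangement_score(arr, os)
  for (c_scale in c(2, 7, 0.5)) {
    scaled <- arr
    scaled$rank_a <- arr$rank_a * c_scale
    expect_equal(arrangement_score(scaled, os), base, tolerance = 1e-12)
  }
})

test_that("synteny matrix is symmetric with unit diagonal and missing zeros", {
  set.seed(505)
  orders <- list(A = gene_order("A", paste0("a", 1:5), 5000),
                 B = gene_order("B", paste0("b", 1:5), 5000),
                 C = gene_order("C", paste0("c", 1:4), 4000))
  sets <- list(ortholog_set("A", "B", paste0("a", 1:4), paste0("b", c(2, 1, 3, 4))))
  m <- synteny_matrix(orders, sets)
  expect_true(is_symmetric_matrix(m))
  expect_equal(unname(diag(m)), c(1, 1, 1))
  expect_true(zero_is_missing(m))
  # C shares no orthologs: its row is 0 off-diagonal
  expect_equal(unname(unclass(m)["C", c("A", "B")]), c(0, 0))
  expect_gt(unclass(m)["A", "B"], 0)
})

test_that("many-to-many hits are canonicalized greedily by identity", {
  os <- ortholog_set("A", "B",
                     gene_a = c("g1", "g1", "g2", "g3"),
                     gene_b = c("h1", "h2", "h1", "h3"),
                     identity_pct = c(99, 97, 98, 96),
                     aligned_length_bp = c(900, 900, 900, 900))
  canon <- canonicalize_orthologs(os)
  expect_equal(nrow(canon$pairs), 2)  # g1-h1 (99) and g3-h3 (96); g2 loses h1
  expect_setequal(paste(canon$pairs$gene_a, canon$pairs$gene_b),
                  c("g1 h1", "g3 h3"))
  # identity tie broken by longer alignment
  tie <- ortholog_set("A", "B", c("g1", "g1"), c("h1", "h2"),
                      identity_pct = c(98, 98),
                      aligned_length_bp = c(800, 1200))
  expect_identical(canonicalize_orthologs(tie)$pairs$gene_b, "h2")
})

test_that("synteny coverage sums blocks and merges physical overlaps", {
  oa <- gene_order("A", c("g1", "g2"), 1000)
  os <- ortholog_set("A", "B", c("g1", "g2"), c("h1", "h2"),
                     aligned_length_bp = c(200, 300))
  expect_equal(synteny_coverage(oa, os, which = "a"), 0.5)

  none <- ortholog_set("A", "B", character(), character())
  expect_equal(synteny_coverage(oa, none, which = "a"), 0)

  full <- ortholog_set("A", "B", c("g1", "g2"), c("h1", "h2"),
                       aligned_length_bp = c(600, 400))
  feats <- data.frame(gene_id = c("g1", "g2"), start_bp = c(1, 601),
                      end_bp = c(600, 1000))
  expect_equal(synteny_coverage(oa, full, which = "a", features = feats), 1)

  # overlapping blocks use the union length
  ovl <- ortholog_set("A", "B", c("g1", "g2"), c("h1", "h2"),
                      aligned_length_bp = c(600, 400))
  feats2 <- data.frame(gene_id = c("g1", "g2"), start_bp = c(1, 301),
                       end_bp = c(600, 700))
  expect_equal(synteny_coverage(oa, ovl, which = "a", features = feats2), 0.7)

  bad <- gene_order("A", "g1", 0)
  expect_error(synteny_coverage(bad, os, which = "a"), "domain error")
})
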