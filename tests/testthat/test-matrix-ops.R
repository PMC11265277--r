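lm2 <- function(v, kind = "distance", zim = FALSE) {
  labeled_matrix(matrix(v, sqrt(length(v)),
                        dimnames = list(sprintf("s%d", seq_len(sqrt(length(v)))),
                                        sprintf("s%d", seq_len(sqrt(length(v)))))),
                 kind = kind, zero_is_missing = zim)
}

test_that("similarity/distance conversion is the 1 - x involution", {
  s <- lm2(c(1, 0.968, 0.968, 1), kind = "similarity")
  d <- to_distance(s)
  expect_equal(unclass(d)["s1", "s2"], 0.032, tolerance = 1e-12)
  expect_equal(unclass(d)["s1", "s1"], 0)
  back <- to_similarity(d)
  expect_equal(unclass(back)[, ], unclass(s)[, ], tolerance = 1e-15)

  # missing zeros convert verbatim to distance 1
  sparse <- lm2(c(1, 0, 0, 1), kind = "similarity", zim = TRUE)
  expect_equal(unclass(to_distance(sparse))["s1", "s2"], 1)
})

test_that("covariance matches the hand example and its conventions", {
  d <- lm2(c(0, 0.2, 0.2, 0))
  cv <- covariance_matrix(d)
  expect_equal(unclass(cv)[, ],
               matrix(c(0.02, -0.02, -0.02, 0.02), 2,
                      dimnames = list(c("s1", "s2"), c("s1", "s2"))),
               tolerance = 1e-14)
  expect_identical(matrix_kind(cv), "covariance")

  const <- lm2(rep(0.3, 9))
  expect_equal(max(abs(unclass(covariance_matrix(const))[, ])), 0)

  set.seed(1)
  r <- random_distance_matrix(6)
  expect_true(is_symmetric_matrix(covariance_matrix(r), tol = 1e-12))
  expect_error(covariance_matrix(lm2(0.1)), "dimension error")
})

test_that("augmentation reproduces the hand-computed 2x2 chain exactly", {
  d16s <- lm2(c(0, 0.1, 0.1, 0))
  dsyn <- lm2(c(0, 0.2, 0.2, 0))
  # product d16s %*% cov(dsyn) = [[-0.002, 0.002], [0.002, -0.002]]
  aug <- augment(d16s, dsyn)
  expect_equal(unclass(aug)[, ],
               matrix(c(0, 1, 1, 0), 2,
                      dimnames = list(c("s1", "s2"), c("s1", "s2"))),
               tolerance = 1e-14)

  # degenerate: constant synteny distances give the all-zero matrix
  flat <- augment(d16s, lm2(rep(0.4, 4)))
  expect_equal(max(abs(unclass(flat)[, ])), 0)
})

test_that("augmented matrices are symmetric, zero-diagonal, in [0,1]", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(4:9, 1)
    d16s <- random_distance_matrix(n)
    dsyn <- random_distance_matrix(n, labels = matrix_labels(d16s))
    aug <- augment(d16s, dsyn)
    expect_true(is_symmetric_matrix(aug, tol = 1e-12))
    expect_equal(max(abs(diag(aug))), 0)
    expect_gte(min(aug), 0)
    expect_lte(max(aug), 1)
    # non-degenerate normalization hits 0 and 1 exactly (pre-symmetrization)
    raw <- augment(d16s, dsyn, force_symmetric = FALSE, zero_diagonal = FALSE)
    expect_equal(min(raw), 0)
    expect_equal(max(raw), 1)
  }
})

test_that("augmentation commutes with a common label permutation", {
  set.seed(8)
  n <- 6
  d16s <- random_distance_matrix(n)
  dsyn <- random_distance_matrix(n, labels = matrix_labels(d16s))
  perm <- sample(matrix_labels(d16s))
  a1 <- augment(d16s, dsyn)
  a2 <- augment(labeled_matrix(unclass(d16s)[perm, perm], kind = "distance"),
                labeled_matrix(unclass(dsyn)[perm, perm], kind = "distance"))
  expect_equal(unclass(a2)[, ], unclass(a1)[perm, perm], tolerance = 1e-12)

  swapped <- labeled_matrix(unclass(dsyn)[perm, perm], kind = "distance")
  expect_error(augment(d16s, swapped), "label mismatch")
})

test_that("Thr keeps strictly-above-threshold similarities only", {
  s <- labeled_matrix(
    matrix(c(1, 0.85, 0.82, 0.85, 1, 0.5, 0.82, 0.5, 1), 3,
           dimnames = list(c("a", "b", "c"), c("a", "b", "c"))),
    kind = "similarity")
  thr <- reduce_thr(s, threshold_pct = 82)
  expect_equal(unclass(thr)["a", "b"], 0.85)   # kept: 0.85 > 0.82
  expect_equal(unclass(thr)["a", "c"], 0)      # removed: 0.82 is not > 0.82
  expect_equal(unclass(thr)["b", "c"], 0)
  expect_true(zero_is_missing(thr))

  all_low <- labeled_matrix(
    matrix(0.5, 2, 2, dimnames = list(c("a", "b"), c("a", "b"))),
    kind = "similarity")
  expect_equal(max(unclass(reduce_thr(all_low))[, ]), 0)

  # distance-scale input is thresholded on 1 - d
  d <- to_distance(s)
  thr_d <- reduce_thr(d, threshold_pct = 82)
  expect_equal(unclass(thr_d)["a", "b"], 0.15, tolerance = 1e-12)
  expect_equal(unclass(thr_d)["b", "c"], 0)
})

test_that("Rem masks to the reference's non-zero support exactly", {
  set.seed(5)
  m <- random_distance_matrix(4)
  full <- labeled_matrix(matrix(1, 4, 4, dimnames = dimnames(m)), kind = "ani")
  expect_equal(unclass(reduce_rem(m, full))[, ], unclass(m)[, ])

  none <- labeled_matrix(matrix(0, 4, 4, dimnames = dimnames(m)), kind = "ani")
  expect_equal(max(abs(unclass(reduce_rem(m, none))[, ])), 0)

  ref <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  ref[1, 2] <- ref[2, 1] <- 90; ref[2, 3] <- ref[3, 2] <- 85
  refm <- labeled_matrix(ref, kind = "ani")
  mm <- labeled_matrix(matrix(0.4, 3, 3, dimnames = dimnames(ref)),
                       kind = "distance")
  rem <- reduce_rem(mm, refm)
  expect_identical(unclass(rem)[, ] != 0, unclass(refm)[, ] != 0)
  # reduce_rem(m, m) preserves m's support
  expect_identical(unclass(reduce_rem(m, m))[, ] != 0, unclass(m)[, ] != 0)
})

test_that("sparsity counts the zero fraction", {
  expect_equal(sparsity(lm2(rep(0, 4), zim = TRUE)), 1)
  expect_equal(sparsity(labeled_matrix(
    matrix(0.2, 2, 2, dimnames = list(c("a", "b"), c("a", "b"))),
    kind = "distance")), 0)
  expect_equal(sparsity(lm2(c(0, 1, 1, 0))), 0.5)
})
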