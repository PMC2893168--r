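test_that("variance selection orders by variance with stable ties", {
  A <- rbind(c(0, 10, 0, 10), c(1, 1.5, 1, 1.5), c(0, 6, 0, 6), c(3, 3, 3, 3))
  rownames(A) <- c("v5", "v1", "v3", "const")
  expect_identical(variance_selection(A, 2), c("v5", "v3"))
  expect_identical(variance_selection(A, 3), c("v5", "v3", "v1"))
  # constant features excluded from any top-n containing a varying feature
  expect_false("const" %in% variance_selection(A, 3))
  expect_error(variance_selection(A, 0), "out of range")
  expect_error(variance_selection(A, 5), "out of range")
  # invariant to instance-column permutation
  expect_identical(variance_selection(A[, c(3, 1, 4, 2)], 3),
                   variance_selection(A, 3))
})

test_that("variance selection picks both informative and PC1-noise features", {
  sim <- small_planted(seed = 7)
  tru <- sim$truth
  n <- length(tru$informative_ids) + length(tru$pc1_noise_ids)
  top <- variance_selection(sim$matrix, n)
  expect_gt(sum(top %in% tru$informative_ids), 0.9 * length(tru$informative_ids))
  expect_gt(sum(top %in% tru$pc1_noise_ids), 0.9 * length(tru$pc1_noise_ids))
})

test_that("feature entropy selection scores single features correctly", {
  A <- rbind(rep(1, 4), c(1, 0, 0, 0), c(sqrt(3), 1, 0, 0), c(2, 2, 2, 2))
  rownames(A) <- c("uniform", "point", "mixed", "uniform2")
  ent <- apply(unclass(as_expression_matrix(A)), 1, single_feature_entropy)
  expect_equal(unname(ent["uniform"]), 1, tolerance = 1e-12)
  expect_equal(unname(ent["point"]), 0, tolerance = 1e-12)
  expect_equal(unname(ent["mixed"]), 0.405639062229567, tolerance = 1e-10)
  expect_identical(feature_entropy_selection(A, 1), "point")
  expect_identical(feature_entropy_selection(A, 1, order = "high_first"),
                   "uniform")
  # all-zero feature assigned entropy 0 with a warning
  B <- rbind(c(0, 0, 0), c(1, 2, 3), c(4, 4, 4))
  rownames(B) <- c("zero", "a", "b")
  expect_warning(sel <- feature_entropy_selection(B, 1), "all-zero")
  expect_identical(sel, "zero")
  # invariant to instance-column permutation
  expect_identical(feature_entropy_selection(A[, c(2, 4, 1, 3)], 2),
                   feature_entropy_selection(A, 2))
})

test_that("random selection is seeded, uniform and bounded", {
  A <- random_matrix(50, 5, 3)
  expect_identical(random_selection(A, 7, seed = 99),
                   random_selection(A, 7, seed = 99))
  expect_setequal(random_selection(A, 50, seed = 1), rownames(as_expression_matrix(A)))
  expect_error(random_selection(A, 51, seed = 1), "out of range")
  # inclusion frequency approximately n/M over many seeds
  M <- 200
  B <- random_matrix(M, 4, 8)
  ids <- rownames(as_expression_matrix(B))
  hits <- numeric(M)
  names(hits) <- ids
  for (seed in 1:100) {
    sel <- random_selection(B, 10, seed = seed)
    hits[sel] <- hits[sel] + 1
  }
  freq <- hits / 100
  p <- 10 / M
  se3 <- 3 * sqrt(p * (1 - p) / 100)
  expect_lt(abs(mean(freq) - p), 1e-10)       # exact by construction
  expect_lt(max(abs(freq - p)), se3 + 0.03)   # binomial band, generous
})

test_that("jaccard score counts pairs correctly", {
  expect_equal(jaccard_score(c(1, 1, 2, 2), c("x", "x", "y", "y")), 1)
  expect_equal(jaccard_score(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
  expect_equal(jaccard_score(c(1, 1, 1), c(1, 1, 2)), 1 / 3)
  # all-singleton agreement: no co-clustered pairs in either -> 1
  expect_equal(jaccard_score(1:4, 4:1), 1)
  expect_error(jaccard_score(1:3, 1:4), "equal length")
  # symmetric and invariant to label renaming
  set.seed(6)
  for (rep in 1:10) {
    a <- sample(1:3, 12, replace = TRUE)
    b <- sample(1:4, 12, replace = TRUE)
    expect_equal(jaccard_score(a, b), jaccard_score(b, a))
    expect_equal(jaccard_score(letters[a], b), jaccard_score(a, b))
  }
})

test_that("jaccard matches brute-force pair enumeration", {
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    n11 <- n10 <- n01 <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      ca <- a[i] == a[j]; cb <- b[i] == b[j]
      if (ca && cb) n11 <- n11 + 1
      else if (ca) n10 <- n10 + 1
      else if (cb) n01 <- n01 + 1
    }
    expected <- if (n11 + n10 + n01 == 0) 1 else n11 / (n11 + n10 + n01)
    expect_equal(jaccard_score(a, b), expected)
  }
})

test_that("kmeans/jaccard harness recovers planted clusters from informative features", {
  sim <- small_planted(seed = 9)
  labels <- sim$truth$cluster_labels
  ev <- kmeans_jaccard_evaluation(sim$matrix, labels,
                                  sim$truth$informative_ids, k = 3,
                                  repeats = 20, seed = 1, method = "truth")
  expect_s3_class(ev, "uff_evaluation")
  expect_gte(ev$jaccard_mean, 0.95)
  expect_true(ev$jaccard_mean >= 0 && ev$jaccard_mean <= 1)
  # noise-only features do materially worse
  ev_noise <- kmeans_jaccard_evaluation(sim$matrix, labels,
                                        sample(sim$truth$neutral_ids, 30),
                                        k = 3, repeats = 20, seed = 1,
                                        method = "noise")
  expect_lt(ev_noise$jaccard_mean, ev$jaccard_mean)
  # repeats = 1 with a fixed seed is deterministic
  e1 <- kmeans_jaccard_evaluation(sim$matrix, labels,
                                  sim$truth$informative_ids, k = 3,
                                  repeats = 1, seed = 5)
  e2 <- kmeans_jaccard_evaluation(sim$matrix, labels,
                                  sim$truth$informative_ids, k = 3,
                                  repeats = 1, seed = 5)
  expect_identical(e1$jaccard_mean, e2$jaccard_mean)
  expect_error(kmeans_jaccard_evaluation(sim$matrix, labels, character(0), 3),
               "empty")
  expect_error(kmeans_jaccard_evaluation(sim$matrix, labels[-1],
                                         sim$truth$informative_ids, 3),
               "per instance")
})
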