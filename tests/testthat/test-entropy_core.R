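test_that("singular_spectrum computes normalized squared weights", {
  s <- singular_spectrum(diag(2))
  expect_equal(s$singular_values, c(1, 1))
  expect_equal(s$weights, c(0.5, 0.5))
  expect_equal(s$q, 2L)
  expect_equal(s$norm_constant, log(2))

  # rank-1 matrix: all weight on the first component
  r1 <- outer(c(1, 2, 3), c(4, 5))
  s1 <- singular_spectrum(r1)
  expect_equal(s1$weights, c(1, 0), tolerance = 1e-12)

  # singular values (sqrt(3), 1) -> weights (0.75, 0.25)
  s2 <- singular_spectrum(diag(c(sqrt(3), 1)))
  expect_equal(s2$weights, c(0.75, 0.25), tolerance = 1e-12)

  # weights always sum to 1, non-increasing singular values
  for (seed in 1:20) {
    A <- random_matrix(sample(2:15, 1), sample(2:15, 1), seed)
    sp <- singular_spectrum(A)
    expect_equal(sum(sp$weights), 1, tolerance = 1e-10)
    expect_true(all(diff(sp$singular_values) <= 1e-10))
    expect_equal(sp$weights,
                 sp$singular_values^2 / sum(sp$singular_values^2),
                 tolerance = 1e-10)
  }
})

test_that("expression_matrix validates its invariants", {
  expect_error(expression_matrix(matrix(1, 1, 3)), "at least 2")
  expect_error(expression_matrix(matrix(c(1, NA, 2, 3), 2, 2)), "finite")
  expect_error(expression_matrix(matrix(0, 3, 3)), "nonzero")
  expect_error(expression_matrix(matrix(1:4, 2, 2),
                                 feature_ids = c("a", "a")), "unique")
  m <- expression_matrix(matrix(1:6, 2, 3), c("g1", "g2"), c("s1", "s2", "s3"))
  expect_identical(rownames(m), c("g1", "g2"))
})

test_that("svd_entropy hits its limits and stays in [0, 1]", {
  # rank 1 -> 0
  expect_equal(svd_entropy(outer(1:4, 1:3)), 0, tolerance = 1e-12)
  # flat spectrum -> 1
  expect_equal(svd_entropy(diag(3) * 2.5), 1, tolerance = 1e-12)
  # weights (0.75, 0.25), q = 2: binary entropy of 0.75 over log 2
  expect_equal(svd_entropy(diag(c(sqrt(3), 1))), 0.811278124459133,
               tolerance = 1e-10)
  for (seed in 1:50) {
    H <- svd_entropy(random_matrix(sample(2:12, 1), sample(2:12, 1), seed))
    expect_true(H >= 0 && H <= 1)
  }
})

test_that("svd_entropy is invariant to permutation, transpose and scaling", {
  A <- random_matrix(7, 5, 42)
  H <- svd_entropy(A)
  expect_equal(svd_entropy(A[sample(7), ]), H, tolerance = 1e-12)
  expect_equal(svd_entropy(A[, sample(5)]), H, tolerance = 1e-12)
  expect_equal(svd_entropy(t(A)), H, tolerance = 1e-12)
  expect_equal(svd_entropy(A * -3.7), H, tolerance = 1e-12)
})

test_that("gram matrix eigenvalues equal squared singular values", {
  expect_equal(unname(gram_matrix(diag(2))), diag(2))
  f <- c(1, 2, 3)
  G1 <- gram_matrix(rbind(f, 0))
  expect_equal(unname(G1), outer(f, f))
  for (seed in 1:10) {
    A <- random_matrix(sample(5:50, 1), sample(3:20, 1), seed)
    ev <- gram_eigendecomposition(gram_matrix(A))$values
    sv2 <- svd(A, nu = 0, nv = 0)$d^2
    q <- min(dim(A))
    expect_equal(ev[seq_len(q)], sv2, tolerance = 1e-8)
  }
})

test_that("gram_eigendecomposition returns orthonormal vectors and rejects asymmetry", {
  expect_error(gram_eigendecomposition(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
  d <- gram_eigendecomposition(diag(c(4, 1)))
  expect_equal(d$values, c(4, 1))
  for (seed in 1:5) {
    A <- random_matrix(12, 6, seed)
    e <- gram_eigendecomposition(crossprod(A))
    expect_equal(crossprod(e$vectors), diag(6), tolerance = 1e-10)
    expect_equal(e$vectors %*% diag(e$values) %*% t(e$vectors), crossprod(A),
                 tolerance = 1e-8)
    expect_true(all(e$values >= 0))
  }
})

test_that("zero matrix and q = 1 are rejected", {
  expect_error(spectrum_from_squares(c(0, 0), 2), "zero matrix")
  sp <- singular_spectrum(matrix(c(1, 2, 2, 4), 2, 2))  # rank 1, q = 2: fine
  expect_equal(svd_entropy(sp), 0, tolerance = 1e-12)
  sp1 <- spectrum_from_squares(4, q = 1)
  expect_error(svd_entropy(sp1), "rank-bound 1")
})

test_that("spectral objectives agree on extremes and ordering", {
  point <- spectrum_from_squares(c(1, 0, 0), 3)
  flat <- spectrum_from_squares(c(1, 1, 1), 3)
  expect_equal(spectral_objective(point, "neg_sum_squares"), -1)
  expect_equal(spectral_objective(flat, "neg_sum_squares"), -1 / 3)
  expect_equal(spectral_objective(point, "geometric_mean"), 0)
  expect_equal(spectral_objective(flat, "geometric_mean"), 1 / 3)
  mid <- spectrum_from_squares(c(3, 1), 2)
  expect_equal(spectral_objective(mid, "geometric_mean"),
               sqrt(0.75 * 0.25), tolerance = 1e-12)
  expect_error(spectral_objective(flat, "entropy_of_doom"))
  # all three objectives: maximal at uniform, minimal at point mass
  set.seed(11)
  for (rep in 1:20) {
    q <- sample(2:8, 1)
    w <- stats::runif(q)
    sp <- spectrum_from_squares(w, q)
    for (obj in c("svd_entropy", "neg_sum_squares", "geometric_mean")) {
      u <- spectrum_from_squares(rep(1, q), q)
      p <- spectrum_from_squares(c(1, rep(0, q - 1)), q)
      val <- spectral_objective(sp, obj)
      expect_lte(val, spectral_objective(u, obj) + 1e-12)
      expect_gte(val, spectral_objective(p, obj) - 1e-12)
    }
  }
})

test_that("entropy matches the log T - K/T identity", {
  # H * log(q) = log(T) - K/T with T = sum(c_i), K = sum(c_i log c_i)
  for (seed in 1:10) {
    A <- random_matrix(10, 6, seed)
    ci <- gram_eigendecomposition(gram_matrix(A))$values
    ci <- ci[ci > 1e-12]
    T_ <- sum(ci); K_ <- sum(ci * log(ci))
    expect_equal(svd_entropy(A), (log(T_) - K_ / T_) / log(6),
                 tolerance = 1e-10)
  }
})
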