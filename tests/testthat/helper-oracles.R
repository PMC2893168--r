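# Independent brute-force oracles: every leave-one-out quantity is recomputed
# by a full SVD of the physically reduced matrix, never through the Gram
# downdate route the package uses internally.

# SVD-entropy of a plain matrix under an externally supplied normalization
# constant (log q of the FULL matrix in leave-one-out comparisons).
oracle_entropy <- function(A, norm_constant = log(min(dim(A)))) {
  sq <- svd(A, nu = 0, nv = 0)$d^2
  w <- sq / sum(sq)
  w <- w[w > 1e-15]
  -sum(w * log(w)) / norm_constant
}

# Exact leave-one-feature-out score by re-decomposing the reduced matrix.
oracle_feature_score <- function(A, i) {
  nc <- log(min(dim(A)))
  oracle_entropy(A, nc) - oracle_entropy(A[-i, , drop = FALSE], nc)
}

# Exact leave-one-instance-out degree by re-decomposing the reduced matrix.
oracle_instance_degree <- function(A, j) {
  nc <- log(min(dim(A)))
  oracle_entropy(A, nc) - oracle_entropy(A[, -j, drop = FALSE], nc)
}

# Seeded random test matrix with O(1)-scaled entries.
random_matrix <- function(M, N, seed) {
  set.seed(seed)
  matrix(stats::rnorm(M * N, mean = 1), M, N)
}

# Population skewness / excess-free kurtosis.
sample_skewness <- function(x) {
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}
sample_kurtosis <- function(x) {
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  mean((x - m)^4) / s^4
}

# Small planted world used by fast unit tests (same structure as the default
# spec, scaled down).
small_planted <- function(seed = 1, n_outliers = 0) {
  generate_planted_matrix(synthetic_spec(
    M = 300L, N = 24L, n_clusters = 3L, n_informative = 30L,
    n_pc1_noise = 30L, n_outliers = n_outliers, outlier_shift = 350,
    seed = seed))
}
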