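#' Outlier degree of one instance (UDO)
#'
#' The outlier degree of instance j is the leave-one-out change in
#' SVD-entropy, \eqn{degree_j = H(A) - H(A^{-j})}, with \eqn{A^{-j}} the
#' matrix with instance column j deleted and both entropies under the full
#' matrix's normalization constant. Instances whose removal decreases the
#' entropy — i.e. leaves a more homogeneous dataset — get positive degree and
#' are outlier candidates.
#'
#' Computed exactly through the Gram matrix: deleting column j of A deletes
#' row and column j of \eqn{C = A^T A}, and the eigenvalues of that principal
#' submatrix are the exact squared singular values of the reduced matrix.
#'
#' @inheritParams uff_score_exact
#' @param instance_index Integer column index of the instance.
#' @return The degree (a single number).
#' @export
udo_degree <- function(matrix, instance_index) {
  A <- as_expression_matrix(matrix)
  N <- ncol(A)
  if (N < 3L) stop("need at least 3 instances to leave one out")
  if (length(instance_index) != 1L || !is.finite(instance_index) ||
      instance_index != as.integer(instance_index) ||
      instance_index < 1L || instance_index > N)
    stop("'instance_index' out of range")
  C <- gram_matrix(A)
  nc <- log(min(dim(A)))
  H_full <- entropy_from_eigenvalues(eigen(C, symmetric = TRUE, only.values = TRUE)$values, nc)
  Cj <- C[-instance_index, -instance_index, drop = FALSE]
  ev <- eigen(Cj, symmetric = TRUE, only.values = TRUE)$values
  if (sum(pmax(ev, 0)) <= 1e-12 * sum(diag(C)))
    stop("remaining matrix is all-zero; degree undefined")
  H_full - entropy_from_eigenvalues(ev, nc)
}

#' Rank instances by outlier degree (UDO)
#'
#' Computes the leave-one-instance-out entropy degree for every instance,
#' ranks them (rank 1 = largest degree), and flags instances whose degree
#' exceeds mean + 1 SD of the degrees, following the same thresholding rule
#' as the feature ranking.
#'
#' @inheritParams uff_score_exact
#' @inheritParams partition_scores
#' @return A `"udo_report"`: data frame with columns `instance_id`, `degree`,
#'   `rank`, `flagged` (rows in input instance order), with attributes
#'   `mean_degree` and `sd_degree`.
#' @examples
#' sim <- generate_planted_matrix(synthetic_spec(M = 80, N = 12, seed = 1))
#' out <- inject_outlier_instances(sim$matrix, n_outliers = 1,
#'                                 outlier_shift = 120, seed = 2)
#' rank_instances(out$matrix)
#' @export
rank_instances <- function(matrix, sd_flavor = c("population", "sample")) {
  sd_flavor <- match.arg(sd_flavor)
  A <- as_expression_matrix(matrix)
  N <- ncol(A)
  if (N < 3L) stop("need at least 3 instances to leave one out")
  C <- gram_matrix(A)
  nc <- log(min(dim(A)))
  H_full <- entropy_from_eigenvalues(eigen(C, symmetric = TRUE, only.values = TRUE)$values, nc)
  degrees <- vapply(seq_len(N), function(j) {
    ev <- eigen(C[-j, -j, drop = FALSE], symmetric = TRUE, only.values = TRUE)$values
    H_full - entropy_from_eigenvalues(ev, nc)
  }, numeric(1))
  m <- mean(degrees)
  s <- stats::sd(degrees) *
    if (sd_flavor == "population") sqrt((N - 1) / N) else 1
  ord <- order(-degrees)
  ranks <- integer(N)
  ranks[ord] <- seq_len(N)
  structure(
    data.frame(instance_id = colnames(A), degree = degrees, rank = ranks,
               flagged = degrees > m + s, stringsAsFactors = FALSE),
    mean_degree = m, sd_degree = s, matrix_entropy = H_full,
    class = c("udo_report", "data.frame"))
}

#' @export
print.udo_report <- function(x, n = 6L, ...) {
  cat(sprintf("UDO outlier report: %d instances, %d flagged (degree > mean + 1 SD)\n",
              nrow(x), sum(x$flagged)))
  print.data.frame(utils::head(x[order(x$rank), , drop = FALSE], n),
                   row.names = FALSE)
  invisible(x)
}

#' kth-nearest-neighbour outlier ranking
#'
#' The classical distance-based baseline: each instance is scored by the
#' Euclidean distance to its kth nearest neighbouring instance (columns as
#' points in feature space) and ranked in descending order of that distance.
#'
#' @inheritParams uff_score_exact
#' @param k Which neighbour to use (default 5, must be < N).
#' @return Data frame with columns `instance_id`, `knn_distance`, `rank`
#'   (rows in input instance order).
#' @export
knn_outlier_ranking <- function(matrix, k = 5L) {
  A <- as_expression_matrix(matrix)
  N <- ncol(A)
  if (k < 1L || k >= N) stop("'k' must satisfy 1 <= k < number of instances")
  D <- as.matrix(stats::dist(t(unclass(A))))
  kd <- vapply(seq_len(N), function(j) {
    d <- D[j, -j]
    sort(d, partial = k)[k]
  }, numeric(1))
  ord <- order(-kd)
  ranks <- integer(N)
  ranks[ord] <- seq_len(N)
  data.frame(instance_id = colnames(A), knn_distance = kd, rank = ranks,
             stringsAsFactors = FALSE)
}
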