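#' Top-n features by variance
#'
#' The classical variance filter: rank features by the (population) variance
#' of their values over all instances and keep the top n. Unlike UFF, this
#' baseline cannot distinguish cluster-informative features from noisy
#' features whose variance comes from a wide Gaussian profile aligned with
#' the first principal component — it picks from both.
#'
#' @inheritParams uff_score_exact
#' @param n Number of features to select (1..M).
#' @param variance `"population"` (default) or `"sample"`; the choice does
#'   not affect the ordering, only reported values elsewhere.
#' @return Character vector of n feature ids, descending variance, stable ties.
#' @export
variance_selection <- function(matrix, n, variance = c("population", "sample")) {
  variance <- match.arg(variance)
  A <- as_expression_matrix(matrix)
  if (n < 1L || n > nrow(A)) stop("'n' out of range")
  v <- apply(unclass(A), 1, stats::var)
  rownames(A)[order(-v)][seq_len(n)]
}

# Normalized entropy of one feature's values: p_j = x_j^2 / sum(x^2) over the
# N instances, scaled by log(N). An all-zero feature has no defined p; it is
# assigned entropy 0 with a warning.
single_feature_entropy <- function(x) {
  sq <- x^2
  if (sum(sq) == 0) return(NA_real_)
  shannon(sq / sum(sq)) / log(length(x))
}

#' Top-n features by per-feature entropy
#'
#' Scores each feature individually by the normalized entropy of the squared
#' values of that feature over the instances (same normalization formalism as
#' the spectrum weights): uniform profiles score 1, single-spike profiles
#' score 0. Which end is "informative" is data-dependent; the default keeps
#' the lowest-entropy features first.
#'
#' @inheritParams variance_selection
#' @param order `"low_first"` (default) or `"high_first"`.
#' @return Character vector of n feature ids.
#' @export
feature_entropy_selection <- function(matrix, n,
                                      order = c("low_first", "high_first")) {
  order <- match.arg(order)
  A <- as_expression_matrix(matrix)
  if (n < 1L || n > nrow(A)) stop("'n' out of range")
  ent <- apply(unclass(A), 1, single_feature_entropy)
  if (anyNA(ent)) {
    warning("all-zero feature(s) assigned entropy 0")
    ent[is.na(ent)] <- 0
  }
  ord <- if (order == "low_first") order(ent) else order(-ent)
  rownames(A)[ord][seq_len(n)]
}

#' Random feature selection
#'
#' Uniform sample of n features without replacement, reproducible under a
#' seed. Used as the floor baseline in the evaluation harness.
#'
#' @inheritParams variance_selection
#' @param seed RNG seed (NULL uses the current RNG state).
#' @return Character vector of n feature ids.
#' @export
random_selection <- function(matrix, n, seed = NULL) {
  A <- as_expression_matrix(matrix)
  if (n < 1L || n > nrow(A)) stop("'n' out of range")
  with_seed(seed, sample(rownames(A), n))
}

#' Jaccard score between two partitions
#'
#' Pair-counting agreement between a clustering and reference labels: over
#' all unordered instance pairs, with n11 = pairs co-clustered in both
#' partitions and n10 / n01 = pairs co-clustered in exactly one,
#' \deqn{J = n11 / (n11 + n10 + n01).}
#' Invariant to label renaming and symmetric in its arguments. If neither
#' partition co-clusters any pair (all singletons), J is defined as 1.
#'
#' @param clustering,reference Label vectors of equal length (any atomic type).
#' @return J in `[0, 1]`.
#' @examples
#' jaccard_score(c(1, 1, 2, 2), c("a", "a", "b", "b"))  # 1
#' @export
jaccard_score <- function(clustering, reference) {
  if (length(clustering) != length(reference))
    stop("'clustering' and 'reference' must have equal length")
  tab <- table(clustering, reference)
  n11 <- sum(choose(tab, 2))
  n1x <- sum(choose(rowSums(tab), 2))   # co-clustered in 'clustering'
  nx1 <- sum(choose(colSums(tab), 2))   # co-clustered in 'reference'
  denom <- n1x + nx1 - n11              # n11 + n10 + n01
  if (denom == 0) return(1)
  n11 / denom
}

# k-means++ style seeding: first center uniform, then points with probability
# proportional to squared distance to the nearest chosen center.
kmeanspp_centers <- function(points, k) {
  n <- nrow(points)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- colSums((t(points) - points[centers[1], ])^2)
  if (k > 1L) for (j in 2:k) {
    if (all(d2 == 0)) {
      # fewer distinct points than k: fall back to distinct rows if possible
      remaining <- setdiff(seq_len(n), centers[seq_len(j - 1L)])
      centers[j] <- remaining[sample.int(length(remaining), 1L)]
    } else {
      centers[j] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, colSums((t(points) - points[centers[j], ])^2))
  }
  points[centers, , drop = FALSE]
}

#' k-means / Jaccard evaluation of a feature set
#'
#' The clustering-based evaluation harness: restrict the matrix to the given
#' features (raw values, no further preprocessing), cluster the instances
#' with k-means (k-means++-style seeding, up to 300 iterations) `repeats`
#' times under independent seeded initializations, and score each clustering
#' against the reference labels with the Jaccard score.
#'
#' @inheritParams variance_selection
#' @param labels Reference labels, one per instance.
#' @param feature_ids Features to cluster on (subset of rownames).
#' @param k Number of clusters passed to k-means (the same k for every
#'   selection method under comparison).
#' @param repeats Number of clustering repetitions (default 100).
#' @param seed Master seed; each repetition draws its initialization from the
#'   seeded stream.
#' @param method Label recorded in the result (e.g. "uff", "variance").
#' @return Object of class `"uff_evaluation"`: list with `method`,
#'   `n_features`, `jaccard_mean`, `jaccard_sd`, `k`, `repeats`.
#' @export
kmeans_jaccard_evaluation <- function(matrix, labels, feature_ids, k,
                                      repeats = 100L, seed = NULL,
                                      method = "unspecified") {
  A <- as_expression_matrix(matrix)
  if (length(labels) != ncol(A))
    stop("'labels' must have one entry per instance")
  if (length(feature_ids) == 0L) stop("empty feature set")
  if (!all(feature_ids %in% rownames(A)))
    stop("unknown feature id(s) in 'feature_ids'")
  if (k < 2L || k > ncol(A)) stop("'k' must satisfy 2 <= k <= N")
  repeats <- as.integer(repeats)
  if (repeats < 1L) stop("'repeats' must be at least 1")
  points <- t(unclass(A)[feature_ids, , drop = FALSE])
  js <- with_seed(seed, vapply(seq_len(repeats), function(r) {
    centers <- kmeanspp_centers(points, k)
    cl <- suppressWarnings(
      stats::kmeans(points, centers = centers, iter.max = 300L))
    jaccard_score(cl$cluster, labels)
  }, numeric(1)))
  structure(list(method = method, n_features = length(feature_ids),
                 jaccard_mean = mean(js),
                 jaccard_sd = if (repeats > 1L) stats::sd(js) else 0,
                 k = as.integer(k), repeats = repeats),
            class = "uff_evaluation")
}

#' @export
print.uff_evaluation <- function(x, ...) {
  cat(sprintf("%s: %d features, k = %d, %d repeats -> Jaccard %.3f (sd %.3f)\n",
              x$method, x$n_features, x$k, x$repeats,
              x$jaccard_mean, x$jaccard_sd))
  invisible(x)
}
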