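# Normalized entropy from Gram eigenvalues under a fixed normalization
# constant. Eigenvalues are clipped at zero; an all-zero spectrum is an
# error (the corresponding matrix would be all-zero).
entropy_from_eigenvalues <- function(ev, norm_constant) {
  ev <- pmax(ev, 0)
  total <- sum(ev)
  if (total <= 0)
    stop("zero matrix has no defined spectrum weights")
  shannon(ev / total) / norm_constant
}

#' Exact UFF score of one feature
#'
#' The UFF score of feature i is the leave-one-out change in SVD-entropy,
#' \eqn{score_i = H(A) - H(A^{-i})}, where \eqn{A^{-i}} is the matrix with
#' feature row i deleted. Both entropies are normalized by the full matrix's
#' `log(q)` so that scores differ only through spectral change. A positive
#' score means the feature's removal decreases entropy, i.e. the feature
#' increases entropy / decreases redundancy — the features UFF selects.
#'
#' The computation is exact: removing row f from A changes the Gram matrix by
#' the rank-one downdate \eqn{C - f f^T}, whose eigenvalues are the exact
#' squared singular values of the reduced matrix.
#'
#' @param matrix A numeric matrix or [expression_matrix()].
#' @param feature_index Integer row index of the feature to score.
#' @return The exact score (a single number).
#' @seealso [rank_features_exact()] for all features at once.
#' @export
uff_score_exact <- function(matrix, feature_index) {
  A <- as_expression_matrix(matrix)
  M <- nrow(A)
  if (length(feature_index) != 1L || !is.finite(feature_index) ||
      feature_index != as.integer(feature_index) ||
      feature_index < 1L || feature_index > M)
    stop("'feature_index' out of range")
  C <- gram_matrix(A)
  nc <- log(min(dim(A)))
  if (min(dim(A)) < 2L)
    stop("entropy undefined for rank-bound 1 (normalization constant log(q) would be 0)")
  H_full <- entropy_from_eigenvalues(eigen(C, symmetric = TRUE, only.values = TRUE)$values, nc)
  f <- unclass(A)[feature_index, ]
  Cd <- C - tcrossprod(f)
  ev <- eigen(Cd, symmetric = TRUE, only.values = TRUE)$values
  if (sum(pmax(ev, 0)) <= max(1e-12 * sum(diag(C)), 0))
    stop("remaining matrix is all-zero; score undefined")
  H_full - entropy_from_eigenvalues(ev, nc)
}

#' Partition scores into positive / neutral / negative groups
#'
#' The Simple Ranking rule: group `"positive"` if score > mean + 1 SD
#' (the selected features), `"negative"` if score < mean - 1 SD, `"neutral"`
#' otherwise. Inequalities are strict, so a constant score vector is all
#' neutral.
#'
#' @param scores Numeric vector (at least 2 values).
#' @param sd_flavor `"population"` (divide by n; the default) or `"sample"`
#'   (divide by n - 1).
#' @return List with `groups` (character vector), `mean_score`, `sd_score`.
#' @export
partition_scores <- function(scores, sd_flavor = c("population", "sample")) {
  sd_flavor <- match.arg(sd_flavor)
  if (length(scores) < 2L) stop("need at least 2 scores")
  if (!all(is.finite(scores))) stop("scores must be finite")
  m <- mean(scores)
  s <- stats::sd(scores)
  if (sd_flavor == "population")
    s <- s * sqrt((length(scores) - 1) / length(scores))
  groups <- rep("neutral", length(scores))
  groups[scores > m + s] <- "positive"
  groups[scores < m - s] <- "negative"
  list(groups = groups, mean_score = m, sd_score = s)
}

# Assemble a feature score table (shared by exact and fast routes).
# Ranks: 1 = highest score, ties broken by input row order (stable).
feature_score_table <- function(feature_ids, scores, method, matrix_entropy,
                                fast_warning = NA, sd_flavor = "population") {
  part <- partition_scores(scores, sd_flavor)
  ord <- order(-scores)                    # stable for ties
  ranks <- integer(length(scores))
  ranks[ord] <- seq_along(scores)
  tab <- data.frame(feature_id = feature_ids, score = scores, rank = ranks,
                    group = part$groups, stringsAsFactors = FALSE)
  structure(tab,
            mean_score = part$mean_score, sd_score = part$sd_score,
            method = method, matrix_entropy = matrix_entropy,
            fast_warning = fast_warning, sd_flavor = sd_flavor,
            class = c("uff_score_table", "data.frame"))
}

#' @export
print.uff_score_table <- function(x, n = 6L, ...) {
  cat(sprintf("UFF feature scores (%s method): %d features\n",
              attr(x, "method"), nrow(x)))
  cat(sprintf("  matrix SVD-entropy = %.4f%s\n", attr(x, "matrix_entropy"),
              if (isTRUE(attr(x, "fast_warning")))
                "  [WARNING: entropy above threshold; fast scores may deviate from exact]"
              else ""))
  cat(sprintf("  score mean = %.4g, sd = %.4g; groups: %d positive / %d neutral / %d negative\n",
              attr(x, "mean_score"), attr(x, "sd_score"),
              sum(x$group == "positive"), sum(x$group == "neutral"),
              sum(x$group == "negative")))
  top <- x[order(x$rank), , drop = FALSE]
  print.data.frame(utils::head(top, n), row.names = FALSE)
  invisible(x)
}

#' Exact UFF ranking of all features
#'
#' Computes the exact leave-one-out SVD-entropy score for every feature via
#' one Gram matrix plus M exact eigendecompositions of its rank-one
#' downdates, then ranks and partitions the scores with the Simple Ranking
#' mean +/- 1 SD rule.
#'
#' @inheritParams uff_score_exact
#' @inheritParams partition_scores
#' @return A `"uff_score_table"`: a data frame with columns `feature_id`,
#'   `score`, `rank`, `group` (rows in input feature order), carrying
#'   attributes `mean_score`, `sd_score`, `method = "exact"`,
#'   `matrix_entropy`.
#' @examples
#' sim <- generate_planted_matrix(synthetic_spec(M = 60, N = 12, seed = 1))
#' tab <- rank_features_exact(sim$matrix)
#' head(select_features(tab))
#' @export
rank_features_exact <- function(matrix, sd_flavor = c("population", "sample")) {
  sd_flavor <- match.arg(sd_flavor)
  A <- as_expression_matrix(matrix)
  if (min(dim(A)) < 2L)
    stop("entropy undefined for rank-bound 1 (normalization constant log(q) would be 0)")
  Av <- unclass(A)
  C <- crossprod(Av)
  nc <- log(min(dim(A)))
  H_full <- entropy_from_eigenvalues(eigen(C, symmetric = TRUE, only.values = TRUE)$values, nc)
  scores <- vapply(seq_len(nrow(Av)), function(i) {
    ev <- eigen(C - tcrossprod(Av[i, ]), symmetric = TRUE, only.values = TRUE)$values
    H_full - entropy_from_eigenvalues(ev, nc)
  }, numeric(1))
  feature_score_table(rownames(A), scores, method = "exact",
                      matrix_entropy = H_full, sd_flavor = sd_flavor)
}

#' Selected (positive-group) features
#'
#' UFF selects group 1 — the features whose score exceeds mean + 1 SD — as
#' the most relevant ones.
#'
#' @param table A `"uff_score_table"`.
#' @return Character vector of positive-group feature ids ordered by rank
#'   (possibly empty).
#' @export
select_features <- function(table) {
  stopifnot(inherits(table, "uff_score_table"))
  pos <- table[table$group == "positive", , drop = FALSE]
  pos$feature_id[order(pos$rank)]
}
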