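# Normalized entropy of a non-negative mass vector: -(1/log(n)) sum p log p.
normalized_entropy <- function(mass) {
  total <- sum(mass)
  if (total <= 0) stop("all values are zero; entropy undefined")
  shannon(mass / total) / log(length(mass))
}

#' Score entropy (SE) applicability measure
#'
#' An entropy-like measure on the normalized squares of the UFF scores:
#' \eqn{p_i = score_i^2 / \sum_j score_j^2},
#' \eqn{SE = -(1/\log M) \sum_i p_i \log p_i}. SE near 1 means score mass is
#' spread evenly over features (no clear minority of informative features);
#' SE near 0 means a few features dominate.
#'
#' @param scores Numeric vector of UFF scores (length >= 2, not all zero).
#' @return SE in `[0, 1]`.
#' @export
score_entropy_SE <- function(scores) {
  if (length(scores) < 2L) stop("need at least 2 scores")
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (all(scores == 0)) stop("all scores are zero; SE undefined")
  normalized_entropy(scores^2)
}

#' Variance entropy (VE) applicability measure
#'
#' An entropy-like measure on the per-feature variances (variance of each
#' feature's values over all instances, population flavor by default):
#' \eqn{q_i = v_i / \sum_j v_j}, \eqn{VE = -(1/\log M) \sum_i q_i \log q_i}.
#'
#' @inheritParams uff_score_exact
#' @param variance `"population"` (default) or `"sample"`.
#' @return VE in `[0, 1]`.
#' @export
variance_entropy_VE <- function(matrix, variance = c("population", "sample")) {
  variance <- match.arg(variance)
  A <- unclass(as_expression_matrix(matrix))
  v <- apply(A, 1, stats::var)
  if (variance == "population") v <- v * (ncol(A) - 1) / ncol(A)
  if (all(v == 0)) stop("all features are constant; VE undefined")
  normalized_entropy(v)
}

#' Dataset applicability report for UFF
#'
#' Combines SE and VE by their geometric mean and compares against a
#' threshold (default 0.8): datasets with combined score strictly below the
#' threshold are judged suitable for UFF selection. The report also carries
#' the matrix SVD-entropy and the fast-approximation warning flag.
#'
#' @inheritParams uff_score_exact
#' @param table Optionally, a precomputed `"uff_score_table"` for this matrix
#'   (computed with [rank_features_exact()] if omitted).
#' @param threshold Suitability cut on the combined score (default 0.8).
#' @param warn_threshold Matrix-entropy cut for the fast-UFF warning flag
#'   (default 0.1).
#' @return An object of class `"uff_applicability"`: list with `SE`, `VE`,
#'   `combined`, `suitable`, `matrix_entropy`, `fast_warning`, `threshold`.
#' @examples
#' sim <- generate_planted_matrix(synthetic_spec(M = 80, N = 12, seed = 1))
#' applicability_report(sim$matrix)
#' @export
applicability_report <- function(matrix, table = NULL, threshold = 0.8,
                                 warn_threshold = 0.1) {
  if (threshold <= 0 || threshold > 1) stop("'threshold' must lie in (0, 1]")
  A <- as_expression_matrix(matrix)
  if (is.null(table)) table <- rank_features_exact(A)
  if (!inherits(table, "uff_score_table")) stop("'table' must be a uff_score_table")
  if (nrow(table) != nrow(A)) stop("'table' does not match 'matrix'")
  se <- score_entropy_SE(table$score)
  ve <- variance_entropy_VE(A)
  combined <- sqrt(se * ve)
  H <- svd_entropy(A)
  structure(
    list(SE = se, VE = ve, combined = combined,
         suitable = combined < threshold,
         matrix_entropy = H, fast_warning = H > warn_threshold,
         threshold = threshold),
    class = "uff_applicability")
}

#' @export
print.uff_applicability <- function(x, ...) {
  cat("UFF applicability report\n")
  cat(sprintf("  SE (score entropy)    : %.4f\n", x$SE))
  cat(sprintf("  VE (variance entropy) : %.4f\n", x$VE))
  cat(sprintf("  combined (geom. mean) : %.4f  (threshold %.2f)\n",
              x$combined, x$threshold))
  cat(sprintf("  verdict               : %s\n",
              if (x$suitable) "SUITABLE for UFF" else "NOT suitable for UFF"))
  cat(sprintf("  matrix SVD-entropy    : %.4f%s\n", x$matrix_entropy,
              if (x$fast_warning) "  [fast-UFF approximation doubtful]" else ""))
  invisible(x)
}
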