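#' Expression matrix container
#'
#' Wraps a numeric feature-by-instance matrix (features in rows, instances in
#' columns) together with unique feature and instance identifiers, after
#' validating the invariants every downstream computation relies on: all
#' entries finite, at least two rows and two columns, and a nonzero Frobenius
#' norm.
#'
#' @param values Numeric matrix, M features x N instances.
#' @param feature_ids Character vector of length M with unique feature
#'   identifiers. Defaults to existing rownames, else `"f1"..."fM"`.
#' @param instance_ids Character vector of length N with unique instance
#'   identifiers. Defaults to existing colnames, else `"s1"..."sN"`.
#' @return An object of class `"expression_matrix"`: the numeric matrix with
#'   dimnames set, carrying the class attribute. It can be used anywhere a
#'   plain matrix is accepted.
#' @examples
#' m <- expression_matrix(matrix(rnorm(12), 3, 4))
#' dim(m)
#' @export
expression_matrix <- function(values, feature_ids = NULL, instance_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("matrix must have at least 2 features (rows) and 2 instances (columns)")
  if (!all(is.finite(values)))
    stop("matrix entries must all be finite (no NA/NaN/Inf)")
  if (all(values == 0))
    stop("matrix must contain at least one nonzero entry")
  if (is.null(feature_ids)) {
    feature_ids <- rownames(values)
    if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(nrow(values)))
  }
  if (is.null(instance_ids)) {
    instance_ids <- colnames(values)
    if (is.null(instance_ids)) instance_ids <- paste0("s", seq_len(ncol(values)))
  }
  feature_ids <- as.character(feature_ids)
  instance_ids <- as.character(instance_ids)
  if (length(feature_ids) != nrow(values))
    stop("length(feature_ids) must equal nrow(values)")
  if (length(instance_ids) != ncol(values))
    stop("length(instance_ids) must equal ncol(values)")
  if (anyDuplicated(feature_ids))
    stop("feature_ids must be unique")
  if (anyDuplicated(instance_ids))
    stop("instance_ids must be unique")
  dimnames(values) <- list(feature_ids, instance_ids)
  class(values) <- c("expression_matrix", class(values))
  values
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d instances\n", nrow(x), ncol(x)))
  cat(sprintf("  features: %s%s\n", paste(utils::head(rownames(x), 4), collapse = ", "),
              if (nrow(x) > 4) ", ..." else ""))
  cat(sprintf("  instances: %s%s\n", paste(utils::head(colnames(x), 4), collapse = ", "),
              if (ncol(x) > 4) ", ..." else ""))
  invisible(x)
}

# Coerce to a validated expression_matrix (no-op if already one).
as_expression_matrix <- function(x) {
  if (inherits(x, "expression_matrix")) return(x)
  expression_matrix(as.matrix(x))
}

#' Singular spectrum of a matrix
#'
#' Computes the singular values \eqn{s_k} of the matrix and their normalized
#' squared weights \eqn{\rho_k = s_k^2 / \sum_j s_j^2}. The weights form a
#' probability-like vector over the \eqn{q = \min(M, N)} spectral components
#' and are the raw material of the SVD-entropy.
#'
#' @param matrix A numeric matrix or [expression_matrix()].
#' @return An object of class `"singular_spectrum"`: a list with
#'   `singular_values` (non-increasing, length q), `weights` (the
#'   \eqn{\rho_k}, summing to 1), `q`, and `norm_constant` (`log(q)`, the
#'   constant used to scale entropies into \eqn{[0, 1]}).
#' @examples
#' singular_spectrum(diag(2))$weights   # 0.5 0.5
#' @export
singular_spectrum <- function(matrix) {
  A <- as_expression_matrix(matrix)
  sv <- svd(unclass(A), nu = 0, nv = 0)$d
  spectrum_from_squares(sv^2, q = min(dim(A)))
}

#' Build a singular spectrum from squared singular values
#'
#' Constructs a `"singular_spectrum"` directly from squared singular values
#' (equivalently, eigenvalues of the Gram matrix). Negative round-off values
#' are clipped to zero. `q` is the rank bound used for the normalization
#' constant; vectors longer than q (possible when M < N and the N x N Gram
#' matrix carries trailing zero eigenvalues) are truncated to their q largest
#' entries, which hold all the spectral mass.
#'
#' @param sq Squared singular values (any order).
#' @param q Rank bound `min(M, N)` of the originating matrix.
#' @return A `"singular_spectrum"`.
#' @export
spectrum_from_squares <- function(sq, q) {
  sq <- pmax(sq, 0)
  sq <- sort(sq, decreasing = TRUE)
  if (length(sq) > q) sq <- sq[seq_len(q)]
  total <- sum(sq)
  if (total <= 0)
    stop("zero matrix has no defined spectrum weights")
  structure(
    list(singular_values = sqrt(sq),
         weights = sq / total,
         q = as.integer(q),
         norm_constant = log(q)),
    class = "singular_spectrum")
}

#' @export
print.singular_spectrum <- function(x, ...) {
  cat(sprintf("singular_spectrum: q = %d, top weights: %s\n", x$q,
              paste(signif(utils::head(x$weights, 5), 4), collapse = ", ")))
  invisible(x)
}

# Shannon entropy of a non-negative weight vector with the 0*log(0) = 0
# convention; weights below 1e-15 are floored to zero against round-off.
shannon <- function(w) {
  w <- w[w > 1e-15]
  -sum(w * log(w))
}

#' SVD-entropy
#'
#' The normalized Shannon-form entropy of the squared-singular-value weights:
#' \deqn{H = -\frac{1}{\log q} \sum_k \rho_k \log \rho_k.}
#' H lies in \eqn{[0, 1]}: 0 for a rank-1 matrix (one dominant component,
#' maximal redundancy) and 1 for a flat spectrum (no redundancy). The
#' logarithm base cancels against the normalization.
#'
#' @param spectrum A `"singular_spectrum"` (from [singular_spectrum()]) or a
#'   numeric matrix, which is decomposed first.
#' @return A number in `[0, 1]`.
#' @examples
#' svd_entropy(diag(2))  # 1: flat spectrum
#' @export
svd_entropy <- function(spectrum) {
  if (!inherits(spectrum, "singular_spectrum"))
    spectrum <- singular_spectrum(spectrum)
  if (spectrum$q < 2L)
    stop("entropy undefined for rank-bound 1 (normalization constant log(q) would be 0)")
  shannon(spectrum$weights) / spectrum$norm_constant
}

#' Gram matrix of an expression matrix
#'
#' \eqn{C = A^T A}, the N x N instance-space Gram matrix. Its eigenvalues are
#' the squared singular values of A, so the SVD-entropy (and every
#' leave-one-out entropy) can be computed from C alone — the key to both the
#' exact Gram-downdate route and the fast approximation.
#'
#' @param matrix A numeric matrix or [expression_matrix()].
#' @return A symmetric positive-semidefinite N x N matrix.
#' @export
gram_matrix <- function(matrix) {
  A <- unclass(as_expression_matrix(matrix))
  crossprod(A)
}

#' Eigendecomposition of a symmetric PSD matrix
#'
#' Symmetric eigendecomposition with eigenvalues in non-increasing order,
#' tiny negative round-off eigenvalues clipped to zero, and orthonormal
#' eigenvector columns.
#'
#' @param gram Symmetric positive-semidefinite matrix (asymmetry beyond
#'   `1e-8` relative tolerance is an error).
#' @return List with `values` (non-increasing, non-negative) and `vectors`
#'   (orthonormal columns, one per eigenvalue).
#' @export
gram_eigendecomposition <- function(gram) {
  if (!is.matrix(gram) || nrow(gram) != ncol(gram))
    stop("'gram' must be a square matrix")
  scale <- max(abs(gram), 1e-300)
  if (max(abs(gram - t(gram))) > 1e-8 * scale)
    stop("'gram' must be symmetric")
  e <- eigen(gram, symmetric = TRUE)
  e$values <- pmax(e$values, 0)
  e
}

#' Spectral objective functions
#'
#' Alternative scalar objectives on the spectrum weights. All three are
#' monotone in the same sense: maximal when all q singular values are equal
#' and minimal when a single singular value carries all the mass. The
#' SVD-entropy is the default objective used everywhere else in the package.
#'
#' @param spectrum A `"singular_spectrum"`.
#' @param objective One of `"svd_entropy"`, `"neg_sum_squares"` (negative sum
#'   of squared weights), `"geometric_mean"` (geometric mean of the weights).
#' @return A single number.
#' @export
spectral_objective <- function(spectrum,
                               objective = c("svd_entropy", "neg_sum_squares",
                                             "geometric_mean")) {
  objective <- match.arg(objective)
  w <- spectrum$weights
  switch(objective,
         svd_entropy = svd_entropy(spectrum),
         neg_sum_squares = -sum(w^2),
         geometric_mean = {
           if (any(w <= 1e-15)) 0 else exp(mean(log(w)))
         })
}
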