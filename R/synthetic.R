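# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Specification of a planted synthetic expression matrix
#'
#' Describes the generative world the UFF model assumes: a strong shared
#' intensity baseline (dominant first principal component), a minority of
#' cluster-informative features with high mean and variance whose signal is
#' spread over several principal components, a minority of noisy features
#' whose mass lies almost entirely on the first principal component (wide
#' Gaussian profiles), and a majority of near-baseline neutral features.
#'
#' Default magnitudes are chosen once, on microarray-intensity grounds:
#' `baseline_offset = 50` (shared platform baseline), `informative_amplitude
#' = 20` (cluster-specific shift, giving informative features high variance
#' relative to background), `noise_sd = 0.5` (background measurement noise;
#' the PC1-aligned noisy features get wide Gaussian noise of `4 * noise_sd`
#' and baseline multipliers of 3-4x, so their mass concentrates on PC1),
#' and `outlier_shift = 900`, i.e. a per-feature aberration comparable to the
#' informative amplitude spread over all M = 2000 features
#' (`20 * sqrt(2000) ~ 894`).
#'
#' @param M,N Number of features (rows) and instances (columns).
#' @param n_clusters Number of instance clusters (balanced assignment).
#' @param n_informative Number of cluster-informative features.
#' @param n_pc1_noise Number of PC1-aligned noisy features.
#' @param baseline_offset Shared baseline intensity added to every entry.
#' @param informative_amplitude Cluster-specific mean shift.
#' @param noise_sd Background (neutral-feature) noise standard deviation.
#' @param outlier_shift Euclidean norm of the shift applied to injected
#'   outlier instances.
#' @param n_outliers Number of outlier instances to inject (default 0).
#' @param seed RNG seed making generation deterministic.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(M = 2000L, N = 60L, n_clusters = 3L,
                           n_informative = 100L, n_pc1_noise = 100L,
                           baseline_offset = 50, informative_amplitude = 20,
                           noise_sd = 0.5, outlier_shift = 900,
                           n_outliers = 0L, seed = 1L) {
  spec <- list(M = as.integer(M), N = as.integer(N),
               n_clusters = as.integer(n_clusters),
               n_informative = as.integer(n_informative),
               n_pc1_noise = as.integer(n_pc1_noise),
               baseline_offset = baseline_offset,
               informative_amplitude = informative_amplitude,
               noise_sd = noise_sd, outlier_shift = outlier_shift,
               n_outliers = as.integer(n_outliers), seed = as.integer(seed))
  if (spec$M < 2L || spec$N < 2L) stop("M and N must be at least 2")
  if (any(c(spec$n_informative, spec$n_pc1_noise, spec$n_outliers,
            spec$n_clusters) < 0L))
    stop("counts must be non-negative")
  if (spec$n_informative + spec$n_pc1_noise > spec$M)
    stop("n_informative + n_pc1_noise must not exceed M")
  if (spec$n_outliers >= spec$N) stop("n_outliers must be smaller than N")
  if (spec$noise_sd < 0) stop("noise_sd must be non-negative")
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a planted expression matrix with known ground truth
#'
#' Builds a feature-by-instance matrix realizing [synthetic_spec()]:
#' instances are assigned to `n_clusters` balanced groups; informative
#' features receive a non-negative cluster-specific mean shift of magnitude
#' `informative_amplitude`; PC1-aligned noisy features receive a large random
#' constant profile (uniform 3-4 times the baseline) plus wide Gaussian
#' noise (`4 * noise_sd`); neutral features carry only baseline and
#' background noise. `baseline_offset` is added to every entry, creating the
#' dominant first principal component typical of raw intensity data. Values
#' are clipped at zero after assembly (rare by construction) to keep the
#' matrix expression-like. If `n_outliers > 0`, outlier instances are
#' injected afterwards via [inject_outlier_instances()].
#'
#' @param spec A [synthetic_spec()].
#' @return List with `matrix` (an [expression_matrix()]) and `truth`: a list
#'   with `informative_ids`, `pc1_noise_ids`, `neutral_ids`,
#'   `cluster_labels` (integer vector named by instance id), and
#'   `outlier_ids` (character, possibly empty).
#' @export
generate_planted_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    M <- spec$M; N <- spec$N
    feature_ids <- sprintf("f%04d", seq_len(M))
    instance_ids <- sprintf("s%03d", seq_len(N))
    roles <- rep("neutral", M)
    special <- if (spec$n_informative + spec$n_pc1_noise > 0L)
      sample.int(M, spec$n_informative + spec$n_pc1_noise) else integer(0)
    inf_idx <- utils::head(special, spec$n_informative)
    pc1_idx <- utils::tail(special, spec$n_pc1_noise)
    roles[inf_idx] <- "informative"
    roles[pc1_idx] <- "pc1_noise"

    cluster_labels <- rep_len(seq_len(max(spec$n_clusters, 1L)), N)

    values <- spec$baseline_offset +
      matrix(stats::rnorm(M * N, sd = spec$noise_sd), M, N)

    if (length(inf_idx)) {
      target_cluster <- rep_len(seq_len(max(spec$n_clusters, 1L)), length(inf_idx))
      for (i in seq_along(inf_idx)) {
        hit <- cluster_labels == target_cluster[i]
        values[inf_idx[i], hit] <- values[inf_idx[i], hit] +
          spec$informative_amplitude
      }
    }
    if (length(pc1_idx)) {
      amp <- stats::runif(length(pc1_idx), 3, 4) * spec$baseline_offset
      wide <- matrix(stats::rnorm(length(pc1_idx) * N, sd = 4 * spec$noise_sd),
                     length(pc1_idx), N)
      values[pc1_idx, ] <- values[pc1_idx, ] + amp + wide
    }
    values[values < 0] <- 0

    mat <- expression_matrix(values, feature_ids, instance_ids)
    truth <- list(informative_ids = feature_ids[inf_idx],
                  pc1_noise_ids = feature_ids[pc1_idx],
                  neutral_ids = feature_ids[roles == "neutral"],
                  cluster_labels = stats::setNames(cluster_labels, instance_ids),
                  outlier_ids = character(0))
    if (spec$n_outliers > 0L) {
      inj <- inject_outlier_instances(mat, spec$n_outliers, spec$outlier_shift,
                                      seed = NULL)
      mat <- inj$matrix
      truth$outlier_ids <- inj$outlier_ids
    }
    list(matrix = mat, truth = truth)
  })
}

#' Inject outlier instances into a matrix
#'
#' Shifts randomly chosen instance columns by a vector of Euclidean norm
#' `outlier_shift` drawn in a random direction orthogonalized against the
#' leading left-singular direction, so the aberration does not simply inflate
#' the shared baseline component. Shifted values may leave the non-negative
#' range (outliers model aberrant measurements and are not re-clipped).
#'
#' @inheritParams uff_score_exact
#' @param n_outliers Number of columns to shift (must be < N/2).
#' @param outlier_shift Euclidean norm of each shift; 0 with `n_outliers > 0`
#'   triggers a warning (the injected outliers are undetectable).
#' @param seed RNG seed; `NULL` uses (and advances) the current RNG state.
#' @return List with `matrix` (shifted copy) and `outlier_ids`.
#' @export
inject_outlier_instances <- function(matrix, n_outliers, outlier_shift,
                                     seed = NULL) {
  A <- as_expression_matrix(matrix)
  n_outliers <- as.integer(n_outliers)
  if (n_outliers < 0L) stop("n_outliers must be non-negative")
  if (n_outliers >= ncol(A) / 2) stop("n_outliers must be smaller than N/2")
  if (n_outliers == 0L)
    return(list(matrix = A, outlier_ids = character(0)))
  if (outlier_shift == 0)
    warning("outlier_shift = 0: injected outliers are undetectable by construction")
  with_seed(seed, {
    Av <- unclass(A)
    # leading left-singular direction (feature-space profile of PC1)
    e1 <- gram_eigendecomposition(crossprod(Av))
    u1 <- drop(Av %*% e1$vectors[, 1])
    u1 <- u1 / sqrt(sum(u1^2))
    cols <- sample.int(ncol(Av), n_outliers)
    for (j in cols) {
      z <- stats::rnorm(nrow(Av))
      z <- z - sum(z * u1) * u1
      z <- z / sqrt(sum(z^2))
      Av[, j] <- Av[, j] + outlier_shift * z
    }
    list(matrix = expression_matrix(Av, rownames(A), colnames(A)),
         outlier_ids = colnames(A)[sort(cols)])
  })
}
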