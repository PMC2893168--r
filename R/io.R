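#' Read a feature-by-instance matrix from delimited text
#'
#' Expects feature ids in the first column and an instance-id header row. The
#' header may or may not carry a corner label above the id column; both
#' layouts are accepted. Every data cell must parse as a finite number;
#' offending cells are reported with their feature and instance ids.
#'
#' @param path File path.
#' @param delimiter Field delimiter (default tab).
#' @param transpose If TRUE the file holds instances in rows and the parsed
#'   matrix is transposed into the features-in-rows convention.
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(path, delimiter = "\t", transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  first_two <- readLines(path, n = 2L)
  if (length(first_two) < 2L) stop("matrix file needs a header row and at least 2 data rows")
  n_hdr <- length(strsplit(first_two[1], delimiter, fixed = TRUE)[[1]])
  n_dat <- length(strsplit(first_two[2], delimiter, fixed = TRUE)[[1]])
  if (n_dat == n_hdr) {
    corner <- TRUE
  } else if (n_dat == n_hdr + 1L) {
    corner <- FALSE
  } else {
    stop("header has ", n_hdr, " fields but data rows have ", n_dat)
  }
  hdr <- strsplit(first_two[1], delimiter, fixed = TRUE)[[1]]
  instance_ids <- if (corner) hdr[-1] else hdr
  df <- utils::read.table(path, sep = delimiter, skip = 1L, header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "", check.names = FALSE)
  if (ncol(df) != length(instance_ids) + 1L)
    stop("inconsistent number of fields across rows")
  feature_ids <- df[[1]]
  raw <- as.matrix(df[, -1, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  bad <- which(!is.finite(values) | raw == "" | is.na(raw), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf("non-numeric or missing value '%s' at feature '%s', instance '%s'",
                 raw[i, j], feature_ids[i], instance_ids[j]))
  }
  if (transpose) {
    expression_matrix(t(values), feature_ids = instance_ids,
                      instance_ids = feature_ids)
  } else {
    expression_matrix(values, feature_ids = feature_ids,
                      instance_ids = instance_ids)
  }
}

#' Write a matrix as tab-delimited text
#'
#' Inverse of [read_matrix()]: instance-id header (with a `feature_id` corner
#' label) and feature ids in the first column, full precision values.
#'
#' @inheritParams uff_score_exact
#' @param path Output file path.
#' @param delimiter Field delimiter.
#' @export
write_matrix <- function(matrix, path, delimiter = "\t") {
  A <- as_expression_matrix(matrix)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(A)), collapse = delimiter), con)
  body <- apply(unclass(A), 1, function(row)
    paste(sprintf("%.17g", row), collapse = delimiter))
  writeLines(paste(rownames(A), body, sep = delimiter), con)
  invisible(path)
}

# Format a numeric value at full round-trip precision.
fmt_full <- function(x) sprintf("%.17g", x)

#' Write a feature score table as TSV
#'
#' Header comment lines (prefixed `#`) record the method, matrix
#' SVD-entropy, fast-approximation warning state, score mean/SD and SD
#' flavor, followed by columns `rank`, `feature_id`, `score` (full
#' precision), `group`, sorted by rank. [read_score_table()] reproduces the
#' table from the file.
#'
#' @param table A `"uff_score_table"`.
#' @param path Output file path.
#' @param timestamp Include a timestamp comment line (default FALSE, keeping
#'   outputs byte-identical across runs).
#' @export
write_score_table <- function(table, path, timestamp = FALSE) {
  stopifnot(inherits(table, "uff_score_table"))
  con <- file(path, "w")
  on.exit(close(con))
  if (timestamp)
    writeLines(sprintf("# written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), con)
  writeLines(c(
    sprintf("# method: %s", attr(table, "method")),
    sprintf("# matrix_entropy: %s", fmt_full(attr(table, "matrix_entropy"))),
    sprintf("# fast_warning: %s", as.character(attr(table, "fast_warning"))),
    sprintf("# mean_score: %s", fmt_full(attr(table, "mean_score"))),
    sprintf("# sd_score: %s", fmt_full(attr(table, "sd_score"))),
    sprintf("# sd_flavor: %s", attr(table, "sd_flavor")),
    paste("rank", "feature_id", "score", "group", sep = "\t")), con)
  tab <- table[order(table$rank), , drop = FALSE]
  writeLines(paste(tab$rank, tab$feature_id, fmt_full(tab$score), tab$group,
                   sep = "\t"), con)
  invisible(path)
}

#' Read back a feature score table written by [write_score_table()]
#'
#' @param path File path.
#' @return A `"uff_score_table"` (rows in rank order).
#' @export
read_score_table <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^# ", "", ln)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- sub("^[^:]+: ", "", kv)
  }
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          colClasses = c("integer", "character", "numeric",
                                         "character"))
  fw <- meta$fast_warning
  structure(df,
            mean_score = as.numeric(meta$mean_score),
            sd_score = as.numeric(meta$sd_score),
            method = meta$method,
            matrix_entropy = as.numeric(meta$matrix_entropy),
            fast_warning = if (identical(fw, "NA")) NA else as.logical(fw),
            sd_flavor = meta$sd_flavor,
            class = c("uff_score_table", "data.frame"))
}

#' Write a UDO outlier report as TSV
#'
#' Columns `rank`, `instance_id`, `degree`, `flagged` (sorted by rank), plus
#' optional kth-NN comparison columns, with mean/SD threshold metadata in
#' comment lines.
#'
#' @param report A `"udo_report"`.
#' @param path Output file path.
#' @param knn Optional data frame from [knn_outlier_ranking()] to merge in.
#' @param timestamp Include a timestamp comment line.
#' @export
write_outlier_report <- function(report, path, knn = NULL, timestamp = FALSE) {
  stopifnot(inherits(report, "udo_report"))
  con <- file(path, "w")
  on.exit(close(con))
  if (timestamp)
    writeLines(sprintf("# written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), con)
  writeLines(c(
    sprintf("# mean_degree: %s", fmt_full(attr(report, "mean_degree"))),
    sprintf("# sd_degree: %s", fmt_full(attr(report, "sd_degree"))),
    sprintf("# matrix_entropy: %s", fmt_full(attr(report, "matrix_entropy")))), con)
  tab <- report[order(report$rank), , drop = FALSE]
  if (!is.null(knn)) {
    m <- match(tab$instance_id, knn$instance_id)
    tab$knn_distance <- knn$knn_distance[m]
    tab$knn_rank <- knn$rank[m]
    writeLines(paste("rank", "instance_id", "degree", "flagged",
                     "knn_distance", "knn_rank", sep = "\t"), con)
    writeLines(paste(tab$rank, tab$instance_id, fmt_full(tab$degree),
                     tab$flagged, fmt_full(tab$knn_distance), tab$knn_rank,
                     sep = "\t"), con)
  } else {
    writeLines(paste("rank", "instance_id", "degree", "flagged", sep = "\t"), con)
    writeLines(paste(tab$rank, tab$instance_id, fmt_full(tab$degree),
                     tab$flagged, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a two-column labels file
#'
#' Tab-delimited `instance_id<TAB>label` (no header) mapping instances to
#' reference labels for the evaluation harness.
#'
#' @param path File path.
#' @param instance_ids Instance ids to align the labels to (order enforced).
#' @return Character vector of labels in `instance_ids` order.
#' @export
read_labels <- function(path, instance_ids) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "#")
  if (ncol(df) != 2L) stop("labels file must have exactly 2 tab-separated columns")
  m <- match(instance_ids, df[[1]])
  if (anyNA(m))
    stop("labels missing for instance(s): ",
         paste(utils::head(instance_ids[is.na(m)], 5), collapse = ", "))
  df[[2]][m]
}
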