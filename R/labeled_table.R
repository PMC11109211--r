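#' Labeled feature table
#'
#' The container that flows through every stage of the pipeline: a numeric
#' feature matrix, a binary label vector, and per-row provenance that records
#' whether a row is an original sample or was synthesized by a resampler (and,
#' if so, from which rows).
#'
#' @param features numeric matrix, one row per sample; `NA` cells allowed
#'   (treated as missing until [preprocess()]).
#' @param labels integer/numeric vector of 0/1 labels, one per row. By
#'   convention 1 marks the positive (usually minority) class.
#' @param provenance character vector, `"original"` or `"synthetic"` per row.
#'   Defaults to all-original.
#' @param parent_ids list of integer vectors, one per row: the `row_id`s of
#'   the rows a synthetic row was generated from; empty for original rows.
#' @param row_ids integer vector of unique row identifiers. Defaults to
#'   `1:nrow(features)`; resamplers assign fresh ids to synthetic rows so that
#'   parentage can be audited across splits.
#'
#' @return an object of class `labeled_table` with fields `features`,
#'   `labels`, `provenance`, `parent_ids`, `row_ids`.
#' @export
labeled_table <- function(features, labels, provenance = NULL,
                          parent_ids = NULL, row_ids = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  if (n < 2L || ncol(features) < 1L)
    stop("labeled_table requires at least 2 samples and 1 feature")
  labels <- as.integer(labels)
  if (length(labels) != n) stop("labels length must match nrow(features)")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (is.null(provenance)) provenance <- rep("original", n)
  if (!all(provenance %in% c("original", "synthetic")))
    stop("provenance must be 'original' or 'synthetic'")
  if (is.null(parent_ids)) parent_ids <- rep(list(integer(0)), n)
  if (is.null(row_ids)) row_ids <- seq_len(n)
  row_ids <- as.integer(row_ids)
  if (anyDuplicated(row_ids)) stop("row_ids must be unique")
  bad <- (provenance == "synthetic") != (lengths(parent_ids) > 0L)
  if (any(bad))
    stop("parent_ids must be nonempty exactly for synthetic rows")
  structure(
    list(features = features, labels = labels, provenance = provenance,
         parent_ids = parent_ids, row_ids = row_ids),
    class = "labeled_table"
  )
}

#' @export
print.labeled_table <- function(x, ...) {
  cat(sprintf(
    "<labeled_table> %d samples x %d features | %d positive / %d negative | %d synthetic\n",
    nrow(x$features), ncol(x$features), sum(x$labels == 1L),
    sum(x$labels == 0L), sum(x$provenance == "synthetic")))
  invisible(x)
}

#' @export
dim.labeled_table <- function(x) dim(x$features)

#' Subset a labeled table by row
#'
#' Keeps features, labels, provenance, parentage and row ids aligned.
#'
#' @param table a [labeled_table()].
#' @param idx integer row positions to keep.
#' @return a `labeled_table` with the selected rows.
#' @export
lt_subset <- function(table, idx) {
  labeled_table(table$features[idx, , drop = FALSE], table$labels[idx],
                table$provenance[idx], table$parent_ids[idx],
                table$row_ids[idx])
}

#' Append synthetic rows to a labeled table
#'
#' @param table a [labeled_table()].
#' @param features matrix of new rows.
#' @param labels labels of new rows.
#' @param parent_ids list of integer vectors of parent `row_id`s, one per new
#'   row; all must be nonempty.
#' @return a `labeled_table` with the synthetic rows appended, carrying fresh
#'   `row_ids`.
#' @export
lt_append_synthetic <- function(table, features, labels, parent_ids) {
  features <- matrix(as.numeric(features), ncol = ncol(table$features))
  m <- nrow(features)
  if (m == 0L) return(table)
  if (any(lengths(parent_ids) == 0L))
    stop("synthetic rows must have at least one parent")
  new_ids <- max(table$row_ids) + seq_len(m)
  labeled_table(
    rbind(table$features, features),
    c(table$labels, as.integer(labels)),
    c(table$provenance, rep("synthetic", m)),
    c(table$parent_ids, parent_ids),
    c(table$row_ids, new_ids)
  )
}

#' Class balance of a labeled table
#'
#' Balance is the majority-class count divided by the minority-class count,
#' so 1.0 means perfectly balanced and larger values mean more imbalanced.
#'
#' @param table a [labeled_table()].
#' @return a real number >= 1.
#' @export
compute_balance <- function(table) {
  n1 <- sum(table$labels == 1L)
  n0 <- sum(table$labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  max(n0, n1) / min(n0, n1)
}

#' Upfront preprocessing: mean imputation and z-scoring
#'
#' Missing cells are imputed with the column mean, then every column is
#' z-scored (population standard deviation, i.e. divided by n). Constant
#' columns map to all-zeros. This mirrors the common radiomics practice of
#' normalizing the pooled data before any train/test split; that practice is
#' itself a (mild) form of leakage and is reproduced deliberately -- the
#' pipeline studies resampling leakage on top of it, not instead of it.
#'
#' @param table a [labeled_table()].
#' @return a `labeled_table` with no missing values and columns of mean 0 and
#'   (population) SD 1, labels untouched.
#' @export
preprocess <- function(table) {
  X <- table$features
  n <- nrow(X)
  for (j in seq_len(ncol(X))) {
    col <- X[, j]
    miss <- is.na(col)
    if (all(miss)) {
      nm <- if (!is.null(colnames(X))) colnames(X)[j] else as.character(j)
      stop(sprintf("column '%s' is entirely missing; cannot impute", nm))
    }
    if (any(miss)) col[miss] <- mean(col[!miss])
    mu <- mean(col)
    sd_pop <- sqrt(sum((col - mu)^2) / n)
    X[, j] <- if (sd_pop > 0) (col - mu) / sd_pop else rep(0, n)
  }
  out <- table
  out$features <- X
  out
}

#' Read a labeled table from CSV
#'
#' Expects a header row, numeric feature columns and one label column.
#' Missing values may be empty cells or `NA`.
#'
#' @param path CSV file path.
#' @param label_col name of the label column (default `"Target"`).
#' @param positive value of `label_col` coding the positive class. If `NULL`
#'   (default) the labels must already be 0/1.
#' @return a [labeled_table()] with all-original provenance.
#' @export
read_labeled_table <- function(path, label_col = "Target", positive = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, na.strings = c("", "NA"))
  if (!label_col %in% names(df))
    stop(sprintf("label column '%s' not found in %s", label_col, path))
  y_raw <- df[[label_col]]
  df[[label_col]] <- NULL
  if (is.null(positive)) {
    y <- suppressWarnings(as.integer(y_raw))
    if (anyNA(y) || !all(y %in% c(0L, 1L)))
      stop("labels are not 0/1; pass `positive` to designate the positive class")
  } else {
    y <- as.integer(y_raw == positive)
  }
  labeled_table(as.matrix(df), y)
}

#' Write a labeled table to CSV
#'
#' Features first, label column last (default name `"Target"`). Provenance is
#' not serialized; a re-read table is treated as all-original.
#'
#' @param table a [labeled_table()].
#' @param path output CSV path.
#' @param label_col label column name.
#' @return `path`, invisibly.
#' @export
write_labeled_table <- function(table, path, label_col = "Target") {
  X <- table$features
  if (is.null(colnames(X))) colnames(X) <- paste0("feature_", seq_len(ncol(X)))
  df <- as.data.frame(X)
  df[[label_col]] <- table$labels
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
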