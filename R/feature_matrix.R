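#' Labeled feature matrix
#'
#' The central data container downstream of feature extraction: one row per
#' time window, one column per (feature, channel) pair, plus a class label
#' and a repetition label per row.  Column names follow the
#' `"feature:channel"` convention.
#'
#' @param values numeric matrix, windows x (features * channels).
#' @param class character/factor vector of per-row class (movement) labels.
#' @param repetition integer vector of per-row repetition labels.
#' @param features character vector of feature ids making up the columns.
#' @param n_channels number of channels per feature block.
#'
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, class, repetition = NULL,
                           features = NULL, n_channels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  class <- as.character(class)
  if (length(class) != nrow(values)) {
    stop("class labels must match row count")
  }
  if (is.null(repetition)) repetition <- rep(1L, nrow(values))
  repetition <- as.integer(repetition)
  if (length(repetition) != nrow(values)) {
    stop("repetition labels must match row count")
  }
  if (is.null(n_channels)) n_channels <- 1L
  if (is.null(features)) {
    if (ncol(values) %% n_channels != 0L) {
      stop("column count not divisible by n_channels")
    }
    features <- paste0("f", seq_len(ncol(values) / n_channels))
  }
  if (length(features) * n_channels != ncol(values)) {
    stop("column count != n_features * n_channels")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- as.vector(t(outer(features, seq_len(n_channels),
                                          function(f, c) paste0(f, ":", c))))
  }
  if (any(!is.finite(values))) {
    stop("feature matrix contains non-finite values")
  }
  structure(
    list(values = values, class = class, repetition = repetition,
         features = as.character(features),
         n_channels = as.integer(n_channels)),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$values), "windows x", ncol(x$values),
      "columns (", length(x$features), "features x", x$n_channels,
      "channels )\n")
  cat("  classes:", paste(unique(x$class), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Subset the rows of a feature matrix
#'
#' @param fm a `feature_matrix`.
#' @param i row index (logical or integer).
#' @return a `feature_matrix` with the selected rows.
#' @export
fm_rows <- function(fm, i) {
  feature_matrix(fm$values[i, , drop = FALSE], fm$class[i],
                 fm$repetition[i], fm$features, fm$n_channels)
}

#' Select a subset of features (all channels) from a feature matrix
#'
#' Keeps the column blocks of the named features, preserving channel order
#' within each block.
#'
#' @param fm a `feature_matrix`.
#' @param features character vector, subset of `fm$features`.
#' @return a `feature_matrix` restricted to those features.
#' @export
fm_select_features <- function(fm, features) {
  missing_f <- setdiff(features, fm$features)
  if (length(missing_f)) {
    stop("unknown feature(s): ", paste(missing_f, collapse = ", "))
  }
  idx <- unlist(lapply(features, function(f) {
    block <- which(fm$features == f)
    (block - 1L) * fm$n_channels + seq_len(fm$n_channels)
  }))
  feature_matrix(fm$values[, idx, drop = FALSE], fm$class, fm$repetition,
                 features, fm$n_channels)
}

#' Bind the rows of two feature matrices with identical columns
#' @param a,b `feature_matrix` objects with identical feature/channel layout.
#' @return combined `feature_matrix`.
#' @export
fm_rbind <- function(a, b) {
  stopifnot(identical(a$features, b$features),
            identical(a$n_channels, b$n_channels))
  feature_matrix(rbind(a$values, b$values), c(a$class, b$class),
                 c(a$repetition, b$repetition), a$features, a$n_channels)
}

#' Write a feature matrix to CSV
#'
#' Plain CSV with `feature:channel` columns followed by trailing `class` and
#' `repetition` label columns.
#'
#' @param fm a `feature_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- as.data.frame(fm$values, check.names = FALSE)
  df$class <- fm$class
  df$repetition <- fm$repetition
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV file path.
#' @param n_channels channels per feature block (recovered from the
#'   `feature:channel` headers when possible).
#' @return a `feature_matrix`.
#' @export
read_feature_matrix <- function(path, n_channels = NULL) {
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  if (!all(c("class", "repetition") %in% names(df))) {
    stop("malformed feature CSV: missing class/repetition columns")
  }
  lab <- names(df) %in% c("class", "repetition")
  vals <- as.matrix(df[, !lab, drop = FALSE])
  cn <- colnames(vals)
  feats <- unique(sub(":.*$", "", cn))
  if (is.null(n_channels)) {
    n_channels <- ncol(vals) / length(feats)
    if (n_channels != round(n_channels)) {
      stop("cannot infer channel count from headers; pass n_channels")
    }
  }
  feature_matrix(vals, df$class, df$repetition, feats, as.integer(n_channels))
}
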