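#' Labeled feature table
#'
#' The universal data container of the pipeline: a numeric samples x features
#' matrix together with unique sample ids, unique feature names and a
#' two-class label per sample. Labels are normalized to the internal
#' vocabulary `"positive"` / `"negative"`; the one-class protocol treats the
#' negative class as "unknown" at evaluation time.
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param labels Character vector of per-sample labels, one of
#'   `"positive"`/`"negative"`.
#' @param sample_ids Unique sample identifiers; defaults to the rownames of
#'   `values` or `sample_1 ... sample_n`.
#' @param feature_names Unique feature names; defaults to the colnames of
#'   `values` or `f1 ... fp`.
#' @param provenance Free-text tag, e.g. a species code or `"synthetic"`.
#'
#' @return An object of class `feature_table` with elements `values`,
#'   `labels`, `sample_ids`, `feature_names`, `provenance`.
#' @examples
#' x <- matrix(rnorm(20), 10, 2)
#' ft <- feature_table(x, rep(c("positive", "negative"), each = 5))
#' dim(ft$values)
#' @export
feature_table <- function(values, labels, sample_ids = NULL,
                          feature_names = NULL, provenance = "unspecified") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_ctx("`values` must be a numeric matrix")
  }
  n <- nrow(values)
  p <- ncol(values)
  if (is.null(feature_names)) {
    feature_names <- colnames(values)
    if (is.null(feature_names)) {
      feature_names <- if (p > 0) paste0("f", seq_len(p)) else character(0)
    }
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) {
      sample_ids <- if (n > 0) paste0("sample_", seq_len(n)) else character(0)
    }
  }
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop_ctx("length(labels) [%d] does not match row count [%d]",
             length(labels), n)
  }
  if (length(sample_ids) != n || anyDuplicated(sample_ids)) {
    stop_ctx("sample_ids must be %d unique strings", n)
  }
  if (length(feature_names) != p || anyDuplicated(feature_names)) {
    dup <- feature_names[duplicated(feature_names)]
    if (length(dup)) {
      stop_ctx("duplicate feature name(s): %s",
               paste(unique(dup), collapse = ", "))
    }
    stop_ctx("feature_names must be %d unique strings", p)
  }
  bad <- setdiff(unique(labels), c("positive", "negative"))
  if (length(bad)) {
    stop_ctx("labels must be 'positive' or 'negative'; found: %s",
             paste(bad, collapse = ", "))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop_ctx("`values` contains missing or non-finite entries")
  }
  dimnames(values) <- list(sample_ids, feature_names)
  structure(
    list(values = values, labels = labels, sample_ids = sample_ids,
         feature_names = feature_names, provenance = provenance),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d samples x %d features (%d positive, %d negative) [%s]\n",
    nrow(x$values), ncol(x$values), sum(x$labels == "positive"),
    sum(x$labels == "negative"), x$provenance))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Subset a feature table
#'
#' @param table A [feature_table()].
#' @param samples Sample ids or logical/integer row index; `NULL` keeps all.
#' @param features Feature names (order respected); `NULL` keeps all.
#' @return A `feature_table` restricted to the requested rows/columns.
#' @export
ft_subset <- function(table, samples = NULL, features = NULL) {
  stopifnot(inherits(table, "feature_table"))
  ridx <- seq_along(table$sample_ids)
  if (!is.null(samples)) {
    if (is.character(samples)) {
      ridx <- match(samples, table$sample_ids)
      if (anyNA(ridx)) {
        stop_ctx("unknown sample id(s): %s",
                 paste(samples[is.na(ridx)], collapse = ", "))
      }
    } else {
      ridx <- seq_along(table$sample_ids)[samples]
    }
  }
  cidx <- seq_along(table$feature_names)
  if (!is.null(features)) {
    cidx <- match(features, table$feature_names)
    if (anyNA(cidx)) {
      stop_ctx("feature(s) absent from table: %s",
               paste(features[is.na(cidx)], collapse = ", "))
    }
  }
  feature_table(table$values[ridx, cidx, drop = FALSE],
                labels = table$labels[ridx],
                sample_ids = table$sample_ids[ridx],
                feature_names = table$feature_names[cidx],
                provenance = table$provenance)
}

#' Row-bind two feature tables sharing the same features
#'
#' @param a,b `feature_table`s with identical feature names (same order).
#' @return The combined `feature_table`; provenance is taken from `a` when the
#'   two differ.
#' @export
ft_rbind <- function(a, b) {
  stopifnot(inherits(a, "feature_table"), inherits(b, "feature_table"))
  if (!identical(a$feature_names, b$feature_names)) {
    stop_ctx("feature tables have different feature columns")
  }
  ids <- c(a$sample_ids, b$sample_ids)
  if (anyDuplicated(ids)) {
    ids <- make.unique(ids, sep = "_dup")
  }
  feature_table(rbind(a$values, b$values),
                labels = c(a$labels, b$labels),
                sample_ids = ids,
                feature_names = a$feature_names,
                provenance = a$provenance)
}
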