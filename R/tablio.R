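#' Ordered feature selection result
#'
#' @param method Selection method tag: one of `LIG`, `HIG`, `RFS`, `RFC`,
#'   `SFC`, `HIC`, `ZNF`, `PCF`, `COMBINED`.
#' @param dataset_id Identifier of the dataset the selection was computed on.
#' @param features Ordered character vector of selected feature names,
#'   most-preferred first.
#' @param scores Optional numeric scores aligned 1:1 with `features`.
#' @param m The intended selection size; recorded as `length(features)` when
#'   fewer candidates were available.
#' @return An object of class `selection_result`.
#' @export
selection_result <- function(method, dataset_id, features, scores = NULL,
                             m = length(features)) {
  methods_ok <- c("LIG", "HIG", "RFS", "RFC", "SFC", "HIC", "ZNF", "PCF",
                  "COMBINED")
  if (!is.character(method) || length(method) != 1L ||
      !(method %in% methods_ok)) {
    stop_ctx("method must be one of %s", paste(methods_ok, collapse = ", "))
  }
  features <- as.character(features)
  if (anyDuplicated(features)) {
    stop_ctx("selection contains duplicate feature(s): %s",
             paste(unique(features[duplicated(features)]), collapse = ", "))
  }
  if (!is.null(scores)) {
    if (length(scores) != length(features)) {
      stop_ctx("scores (%d) not aligned with features (%d)",
               length(scores), length(features))
    }
    scores <- as.numeric(scores)
  }
  structure(list(method = method, dataset_id = as.character(dataset_id),
                 features = features, scores = scores,
                 m = as.integer(m)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s on %s: %d feature(s) (m=%d)\n",
              x$method, x$dataset_id, length(x$features), x$m))
  if (length(x$features)) {
    head_n <- min(5L, length(x$features))
    cat("  top:", paste(x$features[seq_len(head_n)], collapse = ", "),
        if (length(x$features) > head_n) "..." else "", "\n")
  }
  invisible(x)
}

#' Read a labeled feature table from TSV/CSV
#'
#' Expects a header row; one column holds the class label, every other
#' column (besides `sample_id`, if present) is a numeric feature.
#'
#' @param path Path to the file.
#' @param label_column Name of the label column (default `"label"`).
#' @param positive_label,negative_label Values in the label column mapped to
#'   the internal classes.
#' @param sep Field separator, `"\t"` (default) or `","`.
#' @param provenance Provenance tag for the resulting table; defaults to the
#'   file name.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, label_column = "label",
                               positive_label = "positive",
                               negative_label = "negative",
                               sep = "\t", provenance = NULL) {
  if (!file.exists(path)) stop_ctx("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  hdr <- names(df)
  if (anyDuplicated(hdr)) {
    stop_ctx("duplicate column name(s) in %s: %s", path,
             paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  }
  if (!(label_column %in% hdr)) {
    stop_ctx("label column '%s' not found in %s", label_column, path)
  }
  labels_raw <- as.character(df[[label_column]])
  unknown <- setdiff(unique(labels_raw), c(positive_label, negative_label))
  if (length(unknown)) {
    row <- which(labels_raw %in% unknown)[1]
    stop_ctx("unknown label '%s' at data row %d of %s",
             labels_raw[row], row, path)
  }
  labels <- ifelse(labels_raw == positive_label, "positive", "negative")
  ids <- if ("sample_id" %in% hdr) as.character(df[["sample_id"]]) else NULL
  feat_cols <- setdiff(hdr, c(label_column, "sample_id"))
  vals <- as.matrix(df[feat_cols])
  if (length(feat_cols)) {
    for (j in seq_along(feat_cols)) {
      col <- df[[feat_cols[j]]]
      if (!is.numeric(col)) {
        bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
        stop_ctx("non-numeric value '%s' in feature '%s', data row %d of %s",
                 col[bad], feat_cols[j], bad, path)
      }
    }
    storage.mode(vals) <- "double"
    if (anyNA(vals)) {
      idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
      stop_ctx("missing value in feature '%s', data row %d of %s",
               feat_cols[idx[2]], idx[1], path)
    }
  } else {
    vals <- matrix(numeric(0), nrow = nrow(df), ncol = 0)
  }
  feature_table(vals, labels = labels, sample_ids = ids,
                feature_names = feat_cols,
                provenance = provenance %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a feature table as TSV
#'
#' Deterministic layout: header `sample_id`, `label`, then the feature names
#' in table order; one row per sample; numbers formatted with 6 significant
#' digits.
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  header <- paste(c("sample_id", "label", table$feature_names),
                  collapse = "\t")
  n <- nrow(table$values)
  body <- vapply(seq_len(n), function(i) {
    paste(c(table$sample_ids[i], table$labels[i],
            format_num(table$values[i, ])), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Write / read a feature selection list
#'
#' Plain-text interchange format: comment header lines carrying the method,
#' dataset and intended size, then one feature name per line in rank order
#' (most-preferred first).
#'
#' @param sel A [selection_result()].
#' @param path File path.
#' @return `write_selection` returns `path` invisibly; `read_selection`
#'   returns a [selection_result()].
#' @export
write_selection <- function(sel, path) {
  stopifnot(inherits(sel, "selection_result"))
  hdr <- c(sprintf("# method: %s", sel$method),
           sprintf("# dataset: %s", sel$dataset_id),
           sprintf("# m: %d", sel$m))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, sel$features), con, sep = "\n")
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  if (!file.exists(path)) stop_ctx("file not found: %s", path)
  lines <- readLines(path)
  if (!length(lines)) stop_ctx("empty selection file: %s", path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    pat <- sprintf("^#\\s*%s:\\s*(.*)$", key)
    hit <- grep(pat, hdr, value = TRUE)
    if (!length(hit)) stop_ctx("selection file %s lacks '# %s:' header",
                               path, key)
    sub(pat, "\\1", hit[1])
  }
  method <- get_field("method")
  dataset <- get_field("dataset")
  m <- as.integer(get_field("m"))
  feats <- lines[!grepl("^#", lines)]
  feats <- feats[nzchar(feats)]
  if (anyDuplicated(feats)) {
    stop_ctx("selection file %s contains duplicate feature '%s'",
             path, feats[duplicated(feats)][1])
  }
  selection_result(method, dataset, feats, m = m)
}
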