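#' Random feature selection (RFS)
#'
#' Draws `m` features uniformly without replacement; deterministic for a
#' fixed `cfg$seed`.
#'
#' @param table A [feature_table()].
#' @param cfg An [fs_config()]; uses `m` and `seed`.
#' @return A [selection_result()].
#' @export
select_rfs <- function(table, cfg = fs_config()) {
  stopifnot(inherits(table, "feature_table"))
  m <- min(cfg$m, length(table$feature_names))
  sel <- with_seed(derive_seed(cfg$seed, 1L, salt = 100L),
                   resample(table$feature_names, m))
  selection_result("RFS", table$provenance, sel, m = m)
}

#' Zero-norm feature selection (ZNF)
#'
#' Candidate features are those with no exactly-zero value among the
#' positive samples; candidates are ranked by the sum of their raw values
#' over the positive samples, largest first (ties by name). Negative rows
#' never influence the result.
#'
#' @inheritParams select_rfs
#' @return A [selection_result()] with positive-class column sums as scores.
#' @export
select_znf <- function(table, cfg = fs_config()) {
  stopifnot(inherits(table, "feature_table"))
  pos <- table$values[table$labels == "positive", , drop = FALSE]
  if (!nrow(pos)) stop_ctx("ZNF requires at least one positive sample")
  nonzero <- colSums(pos == 0) == 0
  cand <- table$feature_names[nonzero]
  sums <- colSums(pos[, nonzero, drop = FALSE])
  ord <- order(-sums, cand, method = "radix")
  m <- min(cfg$m, length(cand))
  idx <- ord[seq_len(m)]
  selection_result("ZNF", table$provenance, cand[idx],
                   scores = unname(sums[idx]), m = m)
}

#' Pearson-correlation redundancy filter (PCF)
#'
#' Every feature receives a redundancy score: the mean absolute Pearson
#' correlation against all other features. Features are ranked by that
#' score ascending — least redundant first — and the top `m` retained.
#' Constant features (undefined correlation) score 0 by convention;
#' correlations against constant features are excluded from the mean.
#'
#' @inheritParams select_rfs
#' @return A [selection_result()] with redundancy scores.
#' @export
select_pcf <- function(table, cfg = fs_config()) {
  stopifnot(inherits(table, "feature_table"))
  p <- length(table$feature_names)
  if (p < 2) stop_ctx("PCF needs at least two features")
  sds <- apply(table$values, 2L, stats::sd)
  ok <- sds > 0
  score <- numeric(p)
  names(score) <- table$feature_names
  if (sum(ok) >= 2) {
    r <- abs(stats::cor(table$values[, ok, drop = FALSE]))
    diag(r) <- NA
    score[ok] <- rowMeans(r, na.rm = TRUE)
  }
  ord <- order(score, table$feature_names, method = "radix")
  m <- min(cfg$m, p)
  idx <- ord[seq_len(m)]
  selection_result("PCF", table$provenance, table$feature_names[idx],
                   scores = unname(score[idx]), m = m)
}

#' Consensus (combined) feature selection across datasets
#'
#' Given per-dataset top-lists, each feature is scored by its frequency —
#' the number of lists it appears in. Features are ordered by frequency
#' descending, ties by mean rank across the lists containing them
#' (ascending), then by name; the top `m` are returned.
#'
#' @param rankings A list of [selection_result()]s or plain character
#'   vectors (ordered, duplicate-free feature lists).
#' @param cfg An [fs_config()]; uses `m`.
#' @param dataset_id Tag for the combined result (default `"combined"`).
#' @return A [selection_result()] with method `COMBINED` and frequency
#'   scores.
#' @export
combine_selections <- function(rankings, cfg = fs_config(),
                               dataset_id = "combined") {
  if (!length(rankings)) stop_ctx("combine_selections needs >= 1 ranking")
  lists <- lapply(rankings, function(r) {
    f <- if (inherits(r, "selection_result")) r$features else as.character(r)
    if (anyDuplicated(f)) stop_ctx("a ranking contains duplicate features")
    f
  })
  feats <- unique(unlist(lists))
  freq <- integer(length(feats))
  ranksum <- numeric(length(feats))
  names(freq) <- names(ranksum) <- feats
  for (f in lists) {
    freq[f] <- freq[f] + 1L
    ranksum[f] <- ranksum[f] + seq_along(f)
  }
  meanrank <- ranksum / freq
  ord <- order(-freq, meanrank, feats, method = "radix")
  m <- min(cfg$m, length(feats))
  idx <- ord[seq_len(m)]
  selection_result("COMBINED", dataset_id, feats[idx],
                   scores = unname(freq[idx]), m = m)
}

#' Run one named selection method
#'
#' Dispatcher used by the pipeline: runs the method named by `method` on
#' `table`, reusing a precomputed `clustering` for the cluster-based
#' selectors.
#'
#' @param method One of `"LIG"`, `"HIG"`, `"RFS"`, `"RFC"`, `"SFC"`,
#'   `"HIC"`, `"ZNF"`, `"PCF"`.
#' @param table A [feature_table()].
#' @param cfg An [fs_config()].
#' @param clustering Optional [cluster_features()] result; computed on
#'   demand for RFC/SFC/HIC when missing.
#' @return A [selection_result()].
#' @export
select_features <- function(method, table, cfg = fs_config(),
                            clustering = NULL) {
  needs_clust <- method %in% c("RFC", "SFC", "HIC")
  if (needs_clust && is.null(clustering)) {
    clustering <- cluster_features(table, cfg)
  }
  switch(method,
         LIG = select_lig(table, cfg),
         HIG = select_hig(table, cfg),
         RFS = select_rfs(table, cfg),
         RFC = select_rfc(clustering, cfg),
         SFC = select_sfc(clustering, cfg),
         HIC = select_hic(table, clustering, cfg),
         ZNF = select_znf(table, cfg),
         PCF = select_pcf(table, cfg),
         stop_ctx("unknown selection method '%s'", method))
}
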