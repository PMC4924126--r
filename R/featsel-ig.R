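#' Feature-selection configuration
#'
#' @param m Selection size (default 50, the set size used for model
#'   training throughout the study design).
#' @param k_clusters Number of feature clusters for the cluster-based
#'   selectors (default 100).
#' @param n_bins Equal-width discretization bins for information gain
#'   (default 10).
#' @param top_for_combined Per-dataset list length fed into the consensus
#'   selection (default 100).
#' @param seed Random seed for RFS/RFC and k-means initialization.
#' @return An object of class `fs_config`.
#' @export
fs_config <- function(m = 50L, k_clusters = 100L, n_bins = 10L,
                      top_for_combined = 100L, seed = 1L) {
  if (!is_count(m, 1L)) stop_ctx("m must be >= 1")
  if (!is_count(k_clusters, 1L)) stop_ctx("k_clusters must be >= 1")
  if (!is_count(n_bins, 2L)) stop_ctx("n_bins must be >= 2")
  if (!is_count(top_for_combined, 1L) || top_for_combined < m) {
    stop_ctx("top_for_combined must be >= m")
  }
  structure(list(m = as.integer(m), k_clusters = as.integer(k_clusters),
                 n_bins = as.integer(n_bins),
                 top_for_combined = as.integer(top_for_combined),
                 seed = as.integer(seed)),
            class = "fs_config")
}

#' Equal-width discretization
#'
#' Bin `i` (0-based) covers `[min + i*w, min + (i+1)*w)` with
#' `w = range/n_bins`; the last bin is closed on the right. A constant
#' input maps every sample to bin 0.
#'
#' @param values Numeric vector.
#' @param n_bins Number of bins (>= 2).
#' @return Integer vector of 0-based bin indices.
#' @export
discretize_equal_width <- function(values, n_bins = 10L) {
  if (!length(values)) stop_ctx("cannot discretize an empty vector")
  if (!is_count(n_bins, 2L)) stop_ctx("n_bins must be >= 2")
  lo <- min(values)
  hi <- max(values)
  if (hi == lo) return(rep(0L, length(values)))
  w <- (hi - lo) / n_bins
  bins <- floor((values - lo) / w)
  bins[bins >= n_bins] <- n_bins - 1L  # right-closed last bin
  as.integer(bins)
}

entropy_bits <- function(x) {
  p <- tabulate(factor(x)) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of a discretized feature about the class label
#'
#' `IG = H(labels) - sum_v P(X=v) H(labels | X=v)`, in bits (log base 2).
#'
#' @param bins Per-sample discrete values (any atomic type).
#' @param labels Per-sample class labels, same length.
#' @return The information gain in bits, within `[0, H(labels)]`.
#' @examples
#' information_gain(c(0, 0, 1, 1), c("+", "+", "-", "-"))  # 1 bit
#' @export
information_gain <- function(bins, labels) {
  if (length(bins) != length(labels)) {
    stop_ctx("bins (%d) and labels (%d) differ in length",
             length(bins), length(labels))
  }
  if (!length(bins)) stop_ctx("bins must be non-empty")
  h <- entropy_bits(labels)
  n <- length(bins)
  cond <- 0
  for (v in unique(bins)) {
    idx <- bins == v
    cond <- cond + sum(idx) / n * entropy_bits(labels[idx])
  }
  max(0, h - cond)
}

#' Rank all features by information gain
#'
#' Each feature is discretized (equal-width, `cfg$n_bins` bins over its
#' observed range on the full dataset) and scored by information gain about
#' the class label. Features are ordered by IG descending; ties are broken
#' by ascending feature name so the ranking is fully deterministic.
#'
#' @param table A [feature_table()] containing both classes.
#' @param cfg An [fs_config()].
#' @return A data.frame with columns `feature`, `ig`, `rank` (1 = highest IG).
#' @export
rank_by_ig <- function(table, cfg = fs_config()) {
  stopifnot(inherits(table, "feature_table"))
  if (length(unique(table$labels)) < 2) {
    stop_ctx("information-gain ranking needs both classes in the table")
  }
  ig <- vapply(seq_along(table$feature_names), function(j) {
    information_gain(discretize_equal_width(table$values[, j], cfg$n_bins),
                     table$labels)
  }, numeric(1))
  ord <- order(-ig, table$feature_names, method = "radix")
  data.frame(feature = table$feature_names[ord], ig = ig[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Highest / lowest information-gain selection
#'
#' `select_hig` keeps the `m` features with highest IG (most informative
#' first); `select_lig` keeps the `m` features with lowest IG (lowest
#' first) — the latter serves as a deliberately poor, negative-control
#' selection.
#'
#' @param table A [feature_table()] with both classes.
#' @param cfg An [fs_config()].
#' @return A [selection_result()] with IG scores.
#' @export
select_hig <- function(table, cfg = fs_config()) {
  rk <- rank_by_ig(table, cfg)
  m <- min(cfg$m, nrow(rk))
  selection_result("HIG", table$provenance, rk$feature[seq_len(m)],
                   scores = rk$ig[seq_len(m)], m = m)
}

#' @rdname select_hig
#' @export
select_lig <- function(table, cfg = fs_config()) {
  rk <- rank_by_ig(table, cfg)
  m <- min(cfg$m, nrow(rk))
  # lowest IG first; ties by ascending feature name
  ord <- order(rk$ig, rk$feature, method = "radix")
  rk <- rk[ord, ]
  selection_result("LIG", table$provenance, rk$feature[seq_len(m)],
                   scores = rk$ig[seq_len(m)], m = m)
}
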