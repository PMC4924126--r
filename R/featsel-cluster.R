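#' Cluster features in standardized sample-space
#'
#' Each feature is z-scored across samples and treated as a point in
#' n-sample-dimensional space; points are partitioned with k-means
#' (seeded, 10 restarts, best within-cluster sum of squares kept). Constant
#' features z-score to the zero vector. When the features contain fewer
#' distinct standardized points than `k_clusters`, each distinct point
#' becomes its own cluster and the remaining cluster ids stay empty
#' (recorded with size 0).
#'
#' @param table A [feature_table()] with at least `k_clusters` features.
#' @param cfg An [fs_config()]; uses `k_clusters` and `seed`.
#' @return An object of class `feature_clustering` with elements
#'   `assignment` (named integer vector, feature -> cluster id in 1..k),
#'   `centroids` (k x n matrix), `sizes`, `k`, `dist_to_centroid` (named,
#'   Euclidean distance of each feature to its cluster centroid) and
#'   `dataset_id`.
#' @export
cluster_features <- function(table, cfg = fs_config()) {
  stopifnot(inherits(table, "feature_table"))
  k <- cfg$k_clusters
  p <- length(table$feature_names)
  if (p < k) {
    stop_ctx("p = %d features but k_clusters = %d; lower k_clusters", p, k)
  }
  z <- scale(table$values)            # per-feature z-score across samples
  z[is.nan(z)] <- 0                   # constant features -> zero vector
  pts <- t(z)                         # features as rows
  rownames(pts) <- table$feature_names

  uniq <- unique(pts)
  if (nrow(uniq) <= k) {
    # Degenerate case: at most one distinct point per cluster.
    key <- apply(pts, 1L, paste, collapse = "\r")
    ukey <- apply(uniq, 1L, paste, collapse = "\r")
    assignment <- match(key, ukey)
    centroids <- matrix(0, k, ncol(pts))
    centroids[seq_len(nrow(uniq)), ] <- uniq
  } else {
    fit <- with_seed(cfg$seed, {
      best <- NULL
      for (r in 1:10) {
        centers <- uniq[sample.int(nrow(uniq), k), , drop = FALSE]
        km <- suppressWarnings(
          stats::kmeans(pts, centers = centers, iter.max = 100L))
        if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
      }
      best
    })
    assignment <- fit$cluster
    centroids <- fit$centers
  }
  names(assignment) <- table$feature_names
  sizes <- tabulate(assignment, nbins = k)
  d <- sqrt(rowSums((pts - centroids[assignment, , drop = FALSE])^2))
  names(d) <- table$feature_names
  structure(list(assignment = assignment, centroids = centroids,
                 sizes = sizes, k = as.integer(k), dist_to_centroid = d,
                 dataset_id = table$provenance),
            class = "feature_clustering")
}

#' @export
print.feature_clustering <- function(x, ...) {
  cat(sprintf("<feature_clustering> %d features in %d clusters (%d non-empty)\n",
              length(x$assignment), x$k, sum(x$sizes > 0)))
  invisible(x)
}

# Members of each non-empty cluster, in ascending cluster-id order.
cluster_members <- function(clustering) {
  split(names(clustering$assignment), clustering$assignment)
}

#' Random-from-clusters selection (RFC)
#'
#' One uniformly random member is drawn from every non-empty cluster; the
#' final set of `m` features is then drawn uniformly from those
#' representatives. The result never contains two members of one cluster.
#'
#' @param clustering A [cluster_features()] result.
#' @param cfg An [fs_config()]; uses `m` and `seed`.
#' @return A [selection_result()].
#' @export
select_rfc <- function(clustering, cfg = fs_config()) {
  stopifnot(inherits(clustering, "feature_clustering"))
  sel <- with_seed(derive_seed(cfg$seed, 1L, salt = 101L), {
    reps <- vapply(cluster_members(clustering),
                   function(members) resample(members, 1L), character(1))
    if (length(reps) > cfg$m) resample(unname(reps), cfg$m) else unname(reps)
  })
  selection_result("RFC", clustering$dataset_id, sel,
                   m = min(cfg$m, length(sel)))
}

#' Size-ordered-clusters selection (SFC)
#'
#' Clusters are ordered by member count, largest first (ties by the
#' lexicographically smallest member name). Walking that order, each
#' cluster contributes its representative — the member closest to the
#' cluster centroid (ties by name) — until `m` features are collected. If
#' the non-empty clusters run out before `m`, further passes take each
#' cluster's next-closest member in the same cluster order.
#'
#' @inheritParams select_rfc
#' @return A [selection_result()].
#' @export
select_sfc <- function(clustering, cfg = fs_config()) {
  stopifnot(inherits(clustering, "feature_clustering"))
  members <- cluster_members(clustering)
  if (!length(members)) stop_ctx("clustering has no non-empty clusters")
  # order members within each cluster by distance to centroid, ties by name
  members <- lapply(members, function(f) {
    f[order(clustering$dist_to_centroid[f], f, method = "radix")]
  })
  first_member <- vapply(members, function(f) min(f), character(1))
  sizes <- lengths(members)
  cl_order <- order(-sizes, first_member, method = "radix")
  members <- members[cl_order]

  out <- character(0)
  pass <- 1L
  total <- sum(sizes)
  m <- min(cfg$m, total)
  while (length(out) < m) {
    for (f in members) {
      if (length(f) >= pass) out <- c(out, f[pass])
      if (length(out) == m) break
    }
    pass <- pass + 1L
  }
  selection_result("SFC", clustering$dataset_id, out, m = m)
}

#' Highest-IG-from-clusters selection (HIC)
#'
#' From every non-empty cluster the member with maximal information gain is
#' taken (ties by name); the representatives are then re-ranked by IG
#' descending and the top `m` kept.
#'
#' @param table The [feature_table()] the clustering was computed on (both
#'   classes required).
#' @inheritParams select_rfc
#' @return A [selection_result()] with IG scores.
#' @export
select_hic <- function(table, clustering, cfg = fs_config()) {
  stopifnot(inherits(table, "feature_table"),
            inherits(clustering, "feature_clustering"))
  if (!setequal(table$feature_names, names(clustering$assignment))) {
    stop_ctx("table and clustering cover different feature sets")
  }
  rk <- rank_by_ig(table, cfg)
  ig <- stats::setNames(rk$ig, rk$feature)
  reps <- vapply(cluster_members(clustering), function(f) {
    f[order(-ig[f], f, method = "radix")][1]
  }, character(1))
  reps <- unname(reps)
  reps <- reps[order(-ig[reps], reps, method = "radix")]
  m <- min(cfg$m, length(reps))
  reps <- reps[seq_len(m)]
  selection_result("HIC", clustering$dataset_id, reps,
                   scores = unname(ig[reps]), m = m)
}
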