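#' One-class classifier configuration
#'
#' @param k_occ Number of k-means centroids fitted to the target (positive)
#'   class; default 5.
#' @param threshold_quantile Quantile of the training nearest-centroid
#'   distances used as rejection radius; default 0.95.
#' @param seed Random seed for centroid initialization.
#' @return An object of class `occ_config`.
#' @export
occ_config <- function(k_occ = 5L, threshold_quantile = 0.95, seed = 1L) {
  if (!is_count(k_occ, 1L)) stop_ctx("k_occ must be >= 1")
  if (!(threshold_quantile > 0 && threshold_quantile <= 1)) {
    stop_ctx("threshold_quantile must lie in (0, 1]")
  }
  structure(list(k_occ = as.integer(k_occ),
                 threshold_quantile = threshold_quantile,
                 seed = as.integer(seed)),
            class = "occ_config")
}

#' Two-class RBF classifier configuration
#'
#' Defaults follow the study design: radial-basis-function kernel
#' `exp(-gamma * ||u - v||^2)` with `gamma = 0.7`, soft-margin penalty
#' `cost = 4.0`, and min-max normalization of all features to `[0, 1]`.
#'
#' @param gamma RBF width parameter (> 0).
#' @param cost Soft-margin penalty (> 0).
#' @param normalize Apply min-max normalization fitted on the training set.
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(gamma = 0.7, cost = 4.0, normalize = TRUE) {
  if (!is.numeric(gamma) || gamma <= 0) stop_ctx("gamma must be > 0")
  if (!is.numeric(cost) || cost <= 0) stop_ctx("cost must be > 0")
  structure(list(gamma = gamma, cost = cost, normalize = isTRUE(normalize)),
            class = "svm_config")
}

#' Min-max normalization
#'
#' `minmax_fit` records per-feature training minima and maxima;
#' `minmax_apply` maps values to `[0, 1]` by `(x - min) / (max - min)`,
#' sends constant training features to 0, and clips test values outside the
#' training range.
#'
#' @param train_values Numeric training matrix (samples x features).
#' @return `minmax_fit`: a list with `mins` and `maxs`. `minmax_apply`: the
#'   normalized matrix.
#' @export
minmax_fit <- function(train_values) {
  if (!is.matrix(train_values) || nrow(train_values) < 1) {
    stop_ctx("minmax_fit needs a matrix with >= 1 row")
  }
  list(mins = apply(train_values, 2L, min),
       maxs = apply(train_values, 2L, max))
}

#' @rdname minmax_fit
#' @param norm_params A `minmax_fit` result.
#' @param values Numeric matrix to normalize (same feature count).
#' @export
minmax_apply <- function(norm_params, values) {
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  if (ncol(values) != length(norm_params$mins)) {
    stop_ctx("minmax_apply: %d columns but %d fitted features",
             ncol(values), length(norm_params$mins))
  }
  rng <- norm_params$maxs - norm_params$mins
  out <- sweep(values, 2L, norm_params$mins, "-")
  safe <- ifelse(rng > 0, rng, 1)
  out <- sweep(out, 2L, safe, "/")
  out[, rng == 0] <- 0     # constant training feature -> 0.0
  out[out < 0] <- 0        # clip below training min
  out[out > 1] <- 1        # clip above training max
  out
}

# Rows of x as points; distance of each to its nearest centroid.
nearest_centroid_dist <- function(x, centroids) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centroids))) -
    2 * x %*% t(centroids) +
    outer(rep(1, nrow(x)), rowSums(centroids^2))
  sqrt(pmax(apply(d2, 1L, min), 0))
}

#' Fit the k-means one-class classifier
#'
#' Trains on positive examples only: fits min-max normalization on the
#' positive rows, clusters them with k-means (`k_occ` centroids, seeded, 10
#' restarts), and sets the rejection radius `tau` to the
#' `threshold_quantile` quantile (inverse ECDF) of each training row's
#' distance to its nearest centroid. At prediction time a sample within
#' `tau` of any centroid is assigned the target class, otherwise it is
#' rejected as unknown.
#'
#' @param positives A [feature_table()] (or numeric matrix) of positive
#'   training rows, already restricted to the selected features.
#' @param cfg An [occ_config()].
#' @return An object of class `occ_model` with `centroids`, `tau`,
#'   `norm_params` and `selected_features`.
#' @export
fit_occ <- function(positives, cfg = occ_config()) {
  x <- if (inherits(positives, "feature_table")) positives$values else positives
  if (!is.matrix(x)) stop_ctx("fit_occ needs a matrix or feature_table")
  if (nrow(x) < cfg$k_occ) {
    stop_ctx("fit_occ: %d training rows < k_occ = %d", nrow(x), cfg$k_occ)
  }
  np <- minmax_fit(x)
  z <- minmax_apply(np, x)
  uniq <- unique(z)
  if (nrow(uniq) <= cfg$k_occ) {
    centroids <- uniq
  } else {
    fit <- with_seed(derive_seed(cfg$seed, 1L, salt = 300L), {
      best <- NULL
      for (r in 1:10) {
        centers <- uniq[sample.int(nrow(uniq), cfg$k_occ), , drop = FALSE]
        km <- suppressWarnings(
          stats::kmeans(z, centers = centers, iter.max = 100L))
        if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
      }
      best
    })
    centroids <- fit$centers
  }
  d <- nearest_centroid_dist(z, centroids)
  # inverse-ECDF quantile: at least ceil(q*n) training rows fall inside tau
  tau <- unname(stats::quantile(d, probs = cfg$threshold_quantile, type = 1))
  feats <- if (inherits(positives, "feature_table")) {
    positives$feature_names
  } else {
    colnames(x) %||% paste0("f", seq_len(ncol(x)))
  }
  structure(list(centroids = centroids, tau = tau, norm_params = np,
                 selected_features = feats, cfg = cfg),
            class = "occ_model")
}

#' Predict with the one-class classifier
#'
#' @param model An [fit_occ()] result.
#' @param samples A [feature_table()] or numeric matrix carrying at least
#'   the model's selected features.
#' @return Character vector of `"target"` / `"unknown"` labels.
#' @export
predict_occ <- function(model, samples) {
  stopifnot(inherits(model, "occ_model"))
  x <- occ_tcc_feature_matrix(samples, model$selected_features)
  z <- minmax_apply(model$norm_params, x)
  d <- nearest_centroid_dist(z, model$centroids)
  ifelse(d <= model$tau, "target", "unknown")
}

# Extract (and order) the model's feature columns from table/matrix input.
occ_tcc_feature_matrix <- function(samples, features) {
  if (inherits(samples, "feature_table")) {
    missing <- setdiff(features, samples$feature_names)
    if (length(missing)) {
      stop_ctx("samples lack model feature(s): %s",
               paste(missing, collapse = ", "))
    }
    samples$values[, features, drop = FALSE]
  } else {
    x <- as.matrix(samples)
    if (!is.null(colnames(x))) {
      missing <- setdiff(features, colnames(x))
      if (length(missing)) {
        stop_ctx("samples lack model feature(s): %s",
                 paste(missing, collapse = ", "))
      }
      x[, features, drop = FALSE]
    } else {
      if (ncol(x) != length(features)) {
        stop_ctx("sample matrix has %d columns; model expects %d",
                 ncol(x), length(features))
      }
      x
    }
  }
}

#' Fit the RBF two-class classifier
#'
#' Min-max normalization is fitted on all training rows (when
#' `cfg$normalize`), then a soft-margin support-vector classifier with
#' kernel `exp(-gamma * ||u - v||^2)` and penalty `cost` is trained.
#' Fitting is deterministic given identical input order.
#'
#' @param train A [feature_table()] containing both classes, restricted to
#'   the selected features.
#' @param cfg An [svm_config()].
#' @return An object of class `tcc_model`.
#' @export
fit_tcc <- function(train, cfg = svm_config()) {
  stopifnot(inherits(train, "feature_table"))
  if (length(unique(train$labels)) < 2) {
    stop_ctx("fit_tcc needs both classes in the training data")
  }
  x <- train$values
  np <- NULL
  if (cfg$normalize) {
    np <- minmax_fit(x)
    x <- minmax_apply(np, x)
  }
  y <- factor(train$labels, levels = c("positive", "negative"))
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                    gamma = cfg$gamma, cost = cfg$cost, scale = FALSE)
  structure(list(fit = fit, norm_params = np,
                 selected_features = train$feature_names, cfg = cfg),
            class = "tcc_model")
}

#' Predict with the RBF two-class classifier
#'
#' @param model An [fit_tcc()] result.
#' @param samples A [feature_table()] or numeric matrix carrying at least
#'   the model's selected features.
#' @return Character vector of `"positive"` / `"negative"` labels.
#' @export
predict_tcc <- function(model, samples) {
  stopifnot(inherits(model, "tcc_model"))
  x <- occ_tcc_feature_matrix(samples, model$selected_features)
  if (!is.null(model$norm_params)) x <- minmax_apply(model$norm_params, x)
  rownames(x) <- NULL
  as.character(stats::predict(model$fit, x))
}
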