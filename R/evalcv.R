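#' Monte-Carlo cross-validation configuration
#'
#' Defaults follow the study protocol: 100 random 90/10 splits for the
#' one-class classifier and 10 for the two-class classifier.
#'
#' @param folds_occ Monte-Carlo repetitions for the one-class learner.
#' @param folds_tcc Repetitions for the two-class learner.
#' @param train_fraction Fraction of samples used for training per split.
#' @param seed Run seed; per-fold seeds derive deterministically from it.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(folds_occ = 100L, folds_tcc = 10L,
                      train_fraction = 0.9, seed = 1L) {
  if (!is_count(folds_occ, 1L) || !is_count(folds_tcc, 1L)) {
    stop_ctx("fold counts must be >= 1")
  }
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop_ctx("train_fraction must lie in (0, 1)")
  }
  structure(list(folds_occ = as.integer(folds_occ),
                 folds_tcc = as.integer(folds_tcc),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "cv_config")
}

#' One Monte-Carlo train/test split
#'
#' Uniform random split without replacement; the training side receives
#' `round(train_fraction * n)` ids, clamped so both sides hold at least one
#' sample.
#'
#' @param ids Character vector of sample ids (n >= 2).
#' @param train_fraction Training fraction in (0, 1).
#' @param fold_seed Integer seed for this split.
#' @return A list with `train` and `test` id vectors (disjoint, covering).
#' @export
split_mc <- function(ids, train_fraction, fold_seed) {
  n <- length(ids)
  if (n < 2) stop_ctx("split_mc needs >= 2 samples")
  n_train <- min(max(round(train_fraction * n), 1L), n - 1L)
  train <- with_seed(fold_seed, resample(ids, n_train))
  list(train = train, test = setdiff(ids, train))
}

#' Confusion-count record for one fold
#'
#' @param fold Fold index.
#' @param TP,FN,TN,FP Confusion counts with the positive (target) class as
#'   the class of interest.
#' @return A one-row data.frame.
#' @export
fold_result <- function(fold, TP, FN, TN, FP) {
  counts <- c(TP = TP, FN = FN, TN = TN, FP = FP)
  if (any(counts < 0)) stop_ctx("confusion counts must be >= 0")
  data.frame(fold = fold, TP = TP, FN = FN, TN = TN, FP = FP)
}

#' Performance metrics of one confusion record
#'
#' `SE = TP/(TP+FN)`, `SP = TN/(TN+FP)`,
#' `ACC_pooled = (TP+TN)/(TP+FN+TN+FP)`, `ACC_balanced = (SE+SP)/2`.
#'
#' @param fr A one-row data.frame with columns `TP`, `FN`, `TN`, `FP` (or a
#'   named vector/list).
#' @return Named numeric vector `SE`, `SP`, `ACC_pooled`, `ACC_balanced`.
#' @export
compute_metrics <- function(fr) {
  TP <- fr[["TP"]]; FN <- fr[["FN"]]; TN <- fr[["TN"]]; FP <- fr[["FP"]]
  if (TP + FN < 1) stop_ctx("no positive samples in the test set")
  if (TN + FP < 1) stop_ctx("no negative samples in the test set")
  se <- TP / (TP + FN)
  sp <- TN / (TN + FP)
  c(SE = se, SP = sp,
    ACC_pooled = (TP + TN) / (TP + FN + TN + FP),
    ACC_balanced = (se + sp) / 2)
}

#' Aggregate fold results into a metric summary
#'
#' Per-metric mean and sample standard deviation (n-1 denominator) across
#' folds; with a single fold the standard deviation is reported as 0 and
#' `n_folds` records the degeneracy.
#'
#' @param folds A data.frame of [fold_result()] rows.
#' @param method,dataset_id,learner Tags carried into the summary.
#' @return An object of class `metric_summary`: the fold table plus
#'   `SE`, `SP`, `ACC_pooled`, `ACC_balanced` means and `sd_SE`, `sd_SP`,
#'   `sd_ACC_pooled`, `sd_ACC_balanced`.
#' @export
aggregate_folds <- function(folds, method = NA_character_,
                            dataset_id = NA_character_,
                            learner = NA_character_) {
  if (!is.data.frame(folds) || !nrow(folds)) {
    stop_ctx("aggregate_folds needs >= 1 fold")
  }
  per <- t(apply(folds[, c("TP", "FN", "TN", "FP")], 1L, compute_metrics))
  means <- colMeans(per)
  sds <- if (nrow(per) > 1) apply(per, 2L, stats::sd) else rep(0, 4)
  names(sds) <- paste0("sd_", colnames(per))
  structure(c(as.list(means), as.list(sds),
              list(folds = cbind(folds, per), n_folds = nrow(folds),
                   method = method, dataset_id = dataset_id,
                   learner = learner)),
            class = "metric_summary")
}

#' @export
print.metric_summary <- function(x, ...) {
  cat(sprintf(
    "<metric_summary> %s/%s/%s over %d fold(s): SE=%.3f SP=%.3f ACC(bal)=%.3f ACC(pool)=%.3f\n",
    x$learner, x$method, x$dataset_id, x$n_folds,
    x$SE, x$SP, x$ACC_balanced, x$ACC_pooled))
  invisible(x)
}

confusion_counts <- function(pred_pos_is, truth_pos) {
  data.frame(TP = sum(pred_pos_is & truth_pos),
             FN = sum(!pred_pos_is & truth_pos),
             TN = sum(!pred_pos_is & !truth_pos),
             FP = sum(pred_pos_is & !truth_pos))
}

#' Monte-Carlo cross-validation of the one-class classifier
#'
#' Per repetition the positive samples are split 90/10 (per
#' `cv$train_fraction`); the model is fitted on the training positives
#' restricted to the selected features; the test set is the held-out
#' positives plus ALL negative rows, injected as the unknown class. A
#' positive predicted `target` is a true positive; a negative predicted
#' `unknown` is a true negative.
#'
#' @param positives A [feature_table()] of positive samples.
#' @param negatives A [feature_table()] of negative samples sharing the
#'   selected features.
#' @param selection A [selection_result()] naming the features to use.
#' @param cv A [cv_config()].
#' @param occ An [occ_config()].
#' @return A [aggregate_folds()] `metric_summary`.
#' @export
mccv_occ <- function(positives, negatives, selection, cv = cv_config(),
                     occ = occ_config()) {
  stopifnot(inherits(positives, "feature_table"),
            inherits(negatives, "feature_table"),
            inherits(selection, "selection_result"))
  feats <- selection$features
  pos <- ft_subset(positives, features = feats)
  neg <- ft_subset(negatives, features = feats)
  folds <- do.call(rbind, lapply(seq_len(cv$folds_occ), function(i) {
    sp <- split_mc(pos$sample_ids, cv$train_fraction,
                   derive_seed(cv$seed, i, salt = 1L))
    model <- fit_occ(ft_subset(pos, samples = sp$train),
                     occ_config(occ$k_occ, occ$threshold_quantile,
                                seed = derive_seed(cv$seed, i, salt = 2L)))
    test <- ft_rbind(ft_subset(pos, samples = sp$test), neg)
    pred <- predict_occ(model, test)
    cbind(fold = i,
          confusion_counts(pred == "target", test$labels == "positive"))
  }))
  aggregate_folds(folds, method = selection$method,
                  dataset_id = selection$dataset_id, learner = "OCC")
}

#' Monte-Carlo cross-validation of the two-class classifier
#'
#' Per repetition the combined dataset is split 90/10, stratified by class
#' so every training split contains both classes; the RBF classifier is
#' fitted on the training split restricted to the selected features and
#' confusion counts are taken on the test split.
#'
#' @param all_data A [feature_table()] containing both classes.
#' @param selection A [selection_result()].
#' @param cv A [cv_config()].
#' @param svm An [svm_config()].
#' @return A [aggregate_folds()] `metric_summary`.
#' @export
mccv_tcc <- function(all_data, selection, cv = cv_config(),
                     svm = svm_config()) {
  stopifnot(inherits(all_data, "feature_table"),
            inherits(selection, "selection_result"))
  dat <- ft_subset(all_data, features = selection$features)
  pos_ids <- dat$sample_ids[dat$labels == "positive"]
  neg_ids <- dat$sample_ids[dat$labels == "negative"]
  if (!length(pos_ids) || !length(neg_ids)) {
    stop_ctx("mccv_tcc needs both classes")
  }
  folds <- do.call(rbind, lapply(seq_len(cv$folds_tcc), function(i) {
    sp_p <- split_mc(pos_ids, cv$train_fraction,
                     derive_seed(cv$seed, i, salt = 11L))
    sp_n <- split_mc(neg_ids, cv$train_fraction,
                     derive_seed(cv$seed, i, salt = 12L))
    model <- fit_tcc(ft_subset(dat, samples = c(sp_p$train, sp_n$train)), svm)
    test <- ft_subset(dat, samples = c(sp_p$test, sp_n$test))
    pred <- predict_tcc(model, test)
    cbind(fold = i,
          confusion_counts(pred == "positive", test$labels == "positive"))
  }))
  aggregate_folds(folds, method = selection$method,
                  dataset_id = selection$dataset_id, learner = "TCC")
}

#' TCC-minus-OCC accuracy comparison table
#'
#' Builds the per-dataset, per-method difference between the two-class and
#' one-class mean accuracies (`TCC_ACC - OCC_ACC`; positive cells mean the
#' two-class learner performed better), adds an `Average` row across
#' datasets, and orders method columns by increasing average difference.
#'
#' @param occ_results,tcc_results Lists of `metric_summary` objects with
#'   matching `(dataset_id, method)` keys.
#' @param accuracy Which accuracy to compare: `"balanced"` (default) or
#'   `"pooled"`.
#' @return A data.frame with a `dataset` column, one column per method, and
#'   a final `Average` row.
#' @export
difference_table <- function(occ_results, tcc_results,
                             accuracy = c("balanced", "pooled")) {
  accuracy <- match.arg(accuracy)
  field <- if (accuracy == "balanced") "ACC_balanced" else "ACC_pooled"
  key <- function(s) paste(s$dataset_id, s$method, sep = "\r")
  occ <- stats::setNames(vapply(occ_results, `[[`, numeric(1), field),
                         vapply(occ_results, key, character(1)))
  tcc <- stats::setNames(vapply(tcc_results, `[[`, numeric(1), field),
                         vapply(tcc_results, key, character(1)))
  if (!setequal(names(occ), names(tcc))) {
    miss <- c(setdiff(names(occ), names(tcc)), setdiff(names(tcc), names(occ)))
    stop_ctx("unmatched (dataset, method) key(s): %s",
             paste(gsub("\r", "/", miss), collapse = ", "))
  }
  datasets <- unique(vapply(occ_results, `[[`, character(1), "dataset_id"))
  methods <- unique(vapply(occ_results, `[[`, character(1), "method"))
  diff <- matrix(NA_real_, length(datasets), length(methods),
                 dimnames = list(datasets, methods))
  for (k in names(occ)) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    diff[parts[1], parts[2]] <- tcc[k] - occ[k]
  }
  if (anyNA(diff)) stop_ctx("incomplete (dataset, method) grid")
  avg <- colMeans(diff)
  ord <- order(avg, colnames(diff), method = "radix")
  diff <- diff[, ord, drop = FALSE]
  out <- rbind(as.data.frame(diff), Average = avg[ord])
  cbind(dataset = c(datasets, "Average"), out, row.names = NULL)
}
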