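test_that("min-max normalization maps, degenerates and clips correctly", {
  np <- minmax_fit(matrix(c(2, 4), 2, 1))
  expect_equal(as.numeric(minmax_apply(np, matrix(c(2, 3, 4), 3, 1))),
               c(0, 0.5, 1))
  expect_equal(as.numeric(minmax_apply(np, matrix(10, 1, 1))), 1)  # clipped
  expect_equal(as.numeric(minmax_apply(np, matrix(-5, 1, 1))), 0)
  np2 <- minmax_fit(matrix(7, 4, 1))
  expect_equal(as.numeric(minmax_apply(np2, matrix(c(7, 9), 2, 1))), c(0, 0))
  expect_error(minmax_apply(np, matrix(1, 1, 3)), "fitted")
})

test_that("a degenerate one-cluster model has zero radius", {
  x <- matrix(1.5, 10, 3)
  m <- fit_occ(x, occ_config(k_occ = 1, seed = 1))
  expect_equal(m$tau, 0)
  expect_equal(unname(predict_occ(m, x)), rep("target", 10))
  expect_error(fit_occ(x[1:2, , drop = FALSE], occ_config(k_occ = 5)),
               "k_occ")
})

test_that("quantile 1.0 keeps every training row inside the radius", {
  set.seed(13)
  x <- matrix(rnorm(60), 20, 3)
  m <- fit_occ(x, occ_config(k_occ = 3, threshold_quantile = 1.0, seed = 1))
  expect_equal(unname(predict_occ(m, x)), rep("target", 20))
})

test_that("OCC centroids recover well-separated blob means", {
  set.seed(14)
  blob1 <- matrix(rnorm(100 * 2, mean = 0, sd = 0.05), 100, 2)
  blob2 <- matrix(rnorm(100 * 2, mean = 1, sd = 0.05), 100, 2)
  x <- rbind(blob1, blob2)
  m <- fit_occ(x, occ_config(k_occ = 2, seed = 1))
  np <- minmax_fit(x)
  means <- rbind(colMeans(minmax_apply(np, blob1)),
                 colMeans(minmax_apply(np, blob2)))
  # each normalized blob mean is within 0.1 of some centroid
  for (i in 1:2) {
    d <- sqrt(rowSums(sweep(m$centroids, 2L, means[i, ])^2))
    expect_lt(min(d), 0.1)
  }
  # far-field rejection
  far <- matrix(c(100, 100), 1, 2)
  expect_equal(unname(predict_occ(m, far)), "unknown")
})

test_that("raising the threshold quantile trades specificity for sensitivity", {
  out <- generate_feature_table(
    synth_config(n_pos = 120, n_neg = 120, p = 20, n_informative = 10,
                 n_weak = 0, n_redundant_blocks = 0, effect_strong = 1.5,
                 zero_inflation = 0, seed = 15))
  tab <- out$table
  pos <- ft_subset(tab, samples = tab$labels == "positive")
  train <- ft_subset(pos, samples = 1:100)
  test <- ft_subset(tab, samples = c(101:120, which(tab$labels == "negative")))
  prev_se <- -1; prev_sp <- 2
  for (q in c(0.5, 0.8, 0.95, 1.0)) {
    m <- fit_occ(train, occ_config(k_occ = 5, threshold_quantile = q,
                                   seed = 2))
    pred <- predict_occ(m, test)
    truth <- test$labels == "positive"
    se <- mean(pred[truth] == "target")
    sp <- mean(pred[!truth] == "unknown")
    expect_gte(se, prev_se)
    expect_lte(sp, prev_sp)
    prev_se <- se; prev_sp <- sp
    # training coverage: at least ceil(q * n) rows inside the radius
    n_in <- sum(predict_occ(m, train) == "target")
    expect_gte(n_in, ceiling(q * nrow(train$values)))
  }
})

test_that("the RBF classifier separates the toy problem deterministically", {
  toy <- separable_toy()
  m <- fit_tcc(toy, svm_config())
  expect_equal(unname(predict_tcc(m, toy)), toy$labels)  # training acc 1.0
  probe <- matrix(c(0.05, 0.05), 1, 2)
  expect_equal(unname(predict_tcc(m, probe)), "positive")
  expect_identical(predict_tcc(m, probe), predict_tcc(m, probe))
  # row-order invariance of predictions
  rev_toy <- ft_subset(toy, samples = rev(toy$sample_ids))
  expect_equal(unname(predict_tcc(m, rev_toy)), rev(toy$labels))
  expect_error(fit_tcc(ft_subset(toy, samples = toy$labels == "positive"),
                       svm_config()), "both classes")
})

test_that("min-max normalization makes the classifier scale-invariant", {
  toy <- separable_toy()
  grid <- as.matrix(expand.grid(seq(0, 1, 0.25), seq(0, 1, 0.25)))
  colnames(grid) <- NULL
  m1 <- fit_tcc(toy, svm_config())
  scaled <- toy
  scaled$values[, 1] <- scaled$values[, 1] * 1000
  m2 <- fit_tcc(feature_table(scaled$values, scaled$labels,
                              provenance = "scaled"), svm_config())
  grid2 <- grid
  grid2[, 1] <- grid2[, 1] * 1000
  expect_equal(predict_tcc(m1, grid), predict_tcc(m2, grid2))
  # duplicating every training row leaves decisions on the grid unchanged
  dup <- ft_rbind(toy, ft_subset(toy, samples = toy$sample_ids))
  m3 <- fit_tcc(dup, svm_config())
  expect_equal(predict_tcc(m1, grid), predict_tcc(m3, grid))
})

test_that("prediction demands the model's features", {
  toy <- separable_toy()
  m <- fit_tcc(toy, svm_config())
  named <- toy$values
  colnames(named) <- c("f1", "other")
  expect_error(predict_tcc(m, named), "lack")
  mo <- fit_occ(ft_subset(toy, samples = toy$labels == "positive"),
                occ_config(k_occ = 1))
  expect_error(predict_occ(mo, named), "lack")
})
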