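test_that("generated tables have the configured shape and labels", {
  cfg <- synth_config(n_pos = 10, n_neg = 10, p = 5, n_informative = 2,
                      n_weak = 0, n_redundant_blocks = 0, seed = 1)
  out <- generate_feature_table(cfg)
  expect_equal(dim(out$table$values), c(20L, 5L))
  expect_equal(sum(out$table$labels == "positive"), 10L)
  expect_equal(length(out$table$feature_names), 5L)
  expect_false(anyNA(out$table$values))
})

test_that("generation is a pure function of the configuration", {
  cfg <- synth_config(n_pos = 15, n_neg = 15, p = 30, n_informative = 3,
                      n_weak = 2, n_redundant_blocks = 2, block_size = 3,
                      zero_inflation = 0.2, seed = 99)
  a <- generate_feature_table(cfg)
  b <- generate_feature_table(cfg)
  expect_identical(a$table$values, b$table$values)
  expect_identical(a$manifest, b$manifest)
  # and a different seed changes the values
  cfg2 <- synth_config(n_pos = 15, n_neg = 15, p = 30, n_informative = 3,
                       n_weak = 2, n_redundant_blocks = 2, block_size = 3,
                       zero_inflation = 0.2, seed = 100)
  expect_false(identical(a$table$values,
                         generate_feature_table(cfg2)$table$values))
})

test_that("invalid configurations are rejected with the violated invariant", {
  expect_error(synth_config(p = 10, n_informative = 8, n_weak = 8),
               "exceeds p")
  expect_error(synth_config(within_block_corr = 1.5), "within_block_corr")
  expect_error(synth_config(zero_inflation = -0.1), "zero_inflation")
  expect_error(synth_config(n_pos = -3), "n_pos")
  expect_error(
    generate_feature_table(synth_config(n_pos = 2, n_neg = 1, p = 5,
                                        n_informative = 0, n_weak = 0,
                                        n_redundant_blocks = 0)),
    "n_neg")
})

test_that("the manifest partitions all columns with the configured counts", {
  cfg <- synth_config(n_pos = 10, n_neg = 10, p = 10, n_informative = 3,
                      n_weak = 2, n_redundant_blocks = 1, block_size = 2,
                      zero_inflation = 0, seed = 5)
  man <- planted_truth(cfg)
  expect_equal(nrow(man), 10L)
  expect_equal(sum(man$role == "informative"), 3L)
  expect_equal(sum(man$role == "weak"), 2L)
  expect_equal(sum(man$role == "redundant"), 2L)
  expect_setequal(unique(man$role),
                  c("informative", "weak", "redundant", "noise"))
  expect_equal(anyDuplicated(man$feature), 0L)
})

test_that("informative columns carry the planted shift; t-tests reject", {
  cfg <- synth_config(n_pos = 250, n_neg = 250, p = 50, n_informative = 20,
                      n_weak = 0, n_redundant_blocks = 0,
                      effect_strong = 1.5, zero_inflation = 0, seed = 7)
  out <- generate_feature_table(cfg)
  pos <- out$table$labels == "positive"
  inf_cols <- which(out$manifest$role == "informative")
  pvals <- vapply(inf_cols, function(j) {
    stats::t.test(out$table$values[pos, j],
                  out$table$values[!pos, j])$p.value
  }, numeric(1))
  expect_gte(sum(pvals < 0.01), 19L)
})

test_that("redundant blocks hit the target correlation and noise is flat", {
  cfg <- synth_config(n_pos = 150, n_neg = 150, p = 40, n_informative = 0,
                      n_weak = 0, n_redundant_blocks = 2, block_size = 5,
                      within_block_corr = 0.8, zero_inflation = 0, seed = 11)
  out <- generate_feature_table(cfg)
  for (b in 1:2) {
    idx <- which(!is.na(out$manifest$block) & out$manifest$block == b)
    r <- stats::cor(out$table$values[, idx])
    off <- r[upper.tri(r)]
    expect_true(all(abs(off - 0.8) < 0.15))
  }
  # noise columns: standardized class-mean shift near zero at n=500/class
  cfg2 <- synth_config(n_pos = 500, n_neg = 500, p = 30, n_informative = 0,
                       n_weak = 0, n_redundant_blocks = 0,
                       zero_inflation = 0, seed = 12)
  out2 <- generate_feature_table(cfg2)
  pos <- out2$table$labels == "positive"
  shift <- vapply(seq_len(30), function(j) {
    x <- out2$table$values[, j]
    abs(mean(x[pos]) - mean(x[!pos])) / stats::sd(x)
  }, numeric(1))
  expect_lt(mean(shift), 0.2)
})

test_that("zero-inflated columns contain exact zeros, others none", {
  cfg <- synth_config(n_pos = 50, n_neg = 50, p = 20, n_informative = 2,
                      n_weak = 0, n_redundant_blocks = 0,
                      zero_inflation = 0.5, seed = 3)
  out <- generate_feature_table(cfg)
  sparse <- which(out$manifest$role == "sparse")
  dense <- which(out$manifest$role != "sparse")
  expect_gt(length(sparse), 0L)
  for (j in sparse) expect_gt(sum(out$table$values[, j] == 0), 0L)
  expect_equal(sum(out$table$values[, dense] == 0), 0L)
})

test_that("manifest shifts agree with empirical moments across seeds", {
  hits <- 0L
  for (s in 1:20) {
    cfg <- synth_config(n_pos = 100, n_neg = 100, p = 20, n_informative = 4,
                        n_weak = 0, n_redundant_blocks = 0,
                        effect_strong = 1.5, zero_inflation = 0, seed = s)
    out <- generate_feature_table(cfg)
    pos <- out$table$labels == "positive"
    shift <- vapply(seq_len(20), function(j) {
      x <- out$table$values[, j]
      abs(mean(x[pos]) - mean(x[!pos])) / stats::sd(x)
    }, numeric(1))
    inf <- out$manifest$role == "informative"
    if (min(shift[inf]) > max(shift[!inf])) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})
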