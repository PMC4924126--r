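test_that("HIG and LIG exhaust and partition the ranking", {
  tab <- toy_table(n_per_class = 12, p = 6)
  cfg <- fs_config(m = 6)
  hig <- select_hig(tab, cfg)
  lig <- select_lig(tab, cfg)
  expect_setequal(hig$features, tab$feature_names)
  expect_setequal(lig$features, tab$feature_names)
  expect_equal(hig$features, rev(lig$features))
  # disjoint halves when p >= 2m and IG values distinct
  cfg3 <- fs_config(m = 3)
  h3 <- select_hig(tab, cfg3)
  l3 <- select_lig(tab, cfg3)
  rk <- rank_by_ig(tab, cfg3)
  if (!anyDuplicated(rk$ig)) {
    expect_length(intersect(h3$features, l3$features), 0)
  }
})

test_that("random feature selection is seeded and uniform", {
  tab <- toy_table(n_per_class = 5, p = 10)
  a <- select_rfs(tab, fs_config(m = 4, seed = 9))
  b <- select_rfs(tab, fs_config(m = 4, seed = 9))
  expect_identical(a$features, b$features)
  expect_equal(select_rfs(tab, fs_config(m = 10))$m, 10L)
  counts <- integer(10)
  names(counts) <- tab$feature_names
  n_draws <- 10000L
  for (s in seq_len(n_draws)) {
    f <- select_rfs(tab, fs_config(m = 1, seed = s))$features
    counts[f] <- counts[f] + 1L
  }
  freq <- counts / n_draws
  expect_true(all(abs(freq - 0.1) <= 0.01))
})

test_that("zero-norm selection follows positive-class sums and zeros", {
  vals <- rbind(c(1, 0, 2),   # positive
                c(2, 3, 2),   # positive
                c(9, 9, 9))   # negative
  tab <- feature_table(vals, c("positive", "positive", "negative"),
                       feature_names = c("f1", "f2", "f3"),
                       provenance = "znf")
  sel <- select_znf(tab, fs_config(m = 1))
  expect_equal(sel$features, "f3")  # f2 disqualified; sums f1=3 < f3=4
  # adding a negative row changes nothing
  tab2 <- ft_rbind(tab, feature_table(matrix(c(0, 0, 0), 1),
                                      "negative",
                                      sample_ids = "extra",
                                      feature_names = c("f1", "f2", "f3")))
  expect_equal(select_znf(tab2, fs_config(m = 1))$features, sel$features)
  # all-positive-entries table: everything kept, ordered by sums
  tab3 <- feature_table(matrix(c(1, 2, 5, 1), 2),
                        c("positive", "positive"),
                        feature_names = c("a", "b"))
  s3 <- select_znf(tab3, fs_config(m = 2))
  expect_equal(s3$features, c("b", "a"))
  onlyneg <- ft_subset(tab, samples = tab$labels == "negative")
  expect_error(select_znf(onlyneg, fs_config()), "positive")
})

test_that("the Pearson filter prefers uncorrelated features", {
  set.seed(4)
  n <- 200
  base <- rnorm(n)
  vals <- cbind(f1 = base, f2 = base, f3 = rnorm(n))
  tab <- feature_table(vals, rep(c("positive", "negative"), each = n / 2),
                       provenance = "pcf")
  sel <- select_pcf(tab, fs_config(m = 1))
  expect_equal(sel$features, "f3")
  all3 <- select_pcf(tab, fs_config(m = 3))
  expect_true(all(all3$scores >= 0 & all3$scores <= 1))
  expect_error(select_pcf(ft_subset(tab, features = "f1"), fs_config()),
               "two features")
})

test_that("consensus selection matches a brute-force frequency count", {
  r <- list(c("f1", "f2"), c("f1", "f3"))
  expect_equal(combine_selections(r, fs_config(m = 1))$features, "f1")
  # single ranking: identity on its own top-m
  one <- list(c("f9", "f2", "f5"))
  expect_equal(combine_selections(one, fs_config(m = 3))$features,
               c("f9", "f2", "f5"))
  set.seed(5)
  rankings <- lapply(1:6, function(i) sample(paste0("f", 1:30), 10))
  comb <- combine_selections(rankings, fs_config(m = 30))
  brute <- table(unlist(rankings))
  for (i in seq_along(comb$features)) {
    expect_equal(comb$scores[i],
                 as.numeric(brute[comb$features[i]]))
  }
  expect_true(all(diff(comb$scores) <= 0))  # frequency non-increasing
  expect_error(combine_selections(list(), fs_config()), "ranking")
})

test_that("all selectors return unique existing names of length min(m, pool)", {
  out <- generate_feature_table(
    synth_config(n_pos = 40, n_neg = 40, p = 30, n_informative = 4,
                 n_weak = 2, n_redundant_blocks = 2, block_size = 3,
                 zero_inflation = 0.2, seed = 6))
  tab <- out$table
  cfg <- fs_config(m = 12, k_clusters = 15, seed = 3)
  clustering <- cluster_features(tab, cfg)
  for (method in c("LIG", "HIG", "RFS", "RFC", "SFC", "HIC", "PCF")) {
    sel <- select_features(method, tab, cfg, clustering)
    expect_equal(anyDuplicated(sel$features), 0L, label = method)
    expect_true(all(sel$features %in% tab$feature_names), label = method)
    expect_length(sel$features, 12L)
    # reruns with the same seed are identical
    sel2 <- select_features(method, tab, cfg, clustering)
    expect_identical(sel$features, sel2$features, label = method)
  }
  # ZNF may legitimately return fewer (zeros among positives disqualify)
  znf <- select_znf(tab, cfg)
  expect_lte(length(znf$features), 12L)
  expect_equal(znf$m, length(znf$features))
})

test_that("planted informative features are recovered by HIG, not LIG", {
  out <- generate_feature_table(
    synth_config(n_pos = 250, n_neg = 250, p = 200, n_informative = 20,
                 n_weak = 0, n_redundant_blocks = 0, effect_strong = 1.5,
                 zero_inflation = 0, seed = 21))
  planted <- out$manifest$feature[out$manifest$role == "informative"]
  cfg <- fs_config(m = 50)
  expect_gte(length(intersect(select_hig(out$table, cfg)$features, planted)),
             18L)
  expect_lte(length(intersect(select_lig(out$table, cfg)$features, planted)),
             1L)
})
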