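#' Configuration for the synthetic feature-table generator
#'
#' Describes a feature table emulating the statistical structure of
#' pre-miRNA feature matrices: a small set of strongly class-shifted
#' (informative) columns, weakly shifted columns, blocks of mutually
#' correlated (redundant) columns, zero-inflated (sparse) columns, and pure
#' noise. The negative class defaults to 980 samples, mirroring the size of
#' the pseudo pre-miRNA reference set commonly used for plant benchmarks.
#'
#' @param n_pos Number of positive-class samples.
#' @param n_neg Number of negative-class samples (default 980).
#' @param p Total number of feature columns.
#' @param n_informative Count of strongly class-shifted features.
#' @param n_weak Count of weakly shifted features.
#' @param n_redundant_blocks Number of correlated feature blocks.
#' @param block_size Features per redundant block.
#' @param within_block_corr Target pairwise Pearson correlation inside a
#'   block, in `[0, 1]`.
#' @param effect_strong Standardized class-mean shift (delta) of informative
#'   features, in units of the within-class standard deviation.
#' @param effect_weak Standardized shift of weak features.
#' @param zero_inflation Fraction of the unstructured (noise-pool) columns
#'   that are zero-inflated; each entry of such a column is exactly `0.0`
#'   with probability 0.5.
#' @param seed Integer random seed; the generator is a pure function of this
#'   configuration.
#'
#' @return An object of class `synth_config`.
#' @seealso [generate_feature_table()], [planted_truth()]
#' @export
synth_config <- function(n_pos = 250, n_neg = 980, p = 1000,
                         n_informative = 30, n_weak = 50,
                         n_redundant_blocks = 30, block_size = 5,
                         within_block_corr = 0.8,
                         effect_strong = 1.5, effect_weak = 0.3,
                         zero_inflation = 0.1, seed = 1L) {
  cfg <- list(n_pos = n_pos, n_neg = n_neg, p = p,
              n_informative = n_informative, n_weak = n_weak,
              n_redundant_blocks = n_redundant_blocks,
              block_size = block_size,
              within_block_corr = within_block_corr,
              effect_strong = effect_strong, effect_weak = effect_weak,
              zero_inflation = zero_inflation, seed = seed)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  for (f in c("n_pos", "n_neg", "p", "n_informative", "n_weak",
              "n_redundant_blocks", "block_size")) {
    if (!is_count(cfg[[f]])) {
      stop_ctx("invalid synth_config: `%s` must be a non-negative integer", f)
    }
  }
  if (cfg$within_block_corr < 0 || cfg$within_block_corr > 1) {
    stop_ctx("invalid synth_config: within_block_corr must lie in [0, 1]")
  }
  if (cfg$zero_inflation < 0 || cfg$zero_inflation > 1) {
    stop_ctx("invalid synth_config: zero_inflation must lie in [0, 1]")
  }
  n_struct <- cfg$n_informative + cfg$n_weak +
    cfg$n_redundant_blocks * cfg$block_size
  if (n_struct > cfg$p) {
    stop_ctx(paste0("invalid synth_config: n_informative + n_weak + ",
                    "n_redundant_blocks*block_size (%d) exceeds p (%d)"),
             n_struct, cfg$p)
  }
  invisible(cfg)
}

#' Column-role manifest implied by a generator configuration
#'
#' The role layout is positional and depends only on the configuration's
#' counts, so every table generated from configurations sharing the same
#' counts (regardless of seed) has the same manifest. Roles partition all
#' `p` columns.
#'
#' @param config A [synth_config()].
#' @return A data.frame with columns `feature`, `role` (one of
#'   `informative`, `weak`, `redundant`, `sparse`, `noise`) and `block`
#'   (redundant block id, `NA` otherwise).
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  p <- config$p
  role <- rep("noise", p)
  block <- rep(NA_integer_, p)
  i <- 0L
  if (config$n_informative > 0) {
    role[i + seq_len(config$n_informative)] <- "informative"
    i <- i + config$n_informative
  }
  if (config$n_weak > 0) {
    role[i + seq_len(config$n_weak)] <- "weak"
    i <- i + config$n_weak
  }
  if (config$n_redundant_blocks > 0 && config$block_size > 0) {
    for (b in seq_len(config$n_redundant_blocks)) {
      idx <- i + seq_len(config$block_size)
      role[idx] <- "redundant"
      block[idx] <- b
      i <- i + config$block_size
    }
  }
  # Zero-inflated columns are carved deterministically from the front of the
  # remaining noise pool.
  pool <- which(role == "noise")
  n_sparse <- round(config$zero_inflation * length(pool))
  if (n_sparse > 0) role[pool[seq_len(n_sparse)]] <- "sparse"
  data.frame(feature = paste0("f", seq_len(p)), role = role, block = block,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic labeled feature table
#'
#' Each feature is Gaussian with unit within-class standard deviation and a
#' baseline mean drawn uniformly from `[1, 3]` (so typical values are
#' positive but the table is deliberately not normalized — normalization is
#' the classifiers' job). Informative and weak columns shift the
#' positive-class mean by `effect_strong` resp. `effect_weak` standard
#' deviations. Redundant blocks are built from a shared latent driver
#' `z` per sample as `sqrt(r)*z + sqrt(1-r)*noise`, giving pairwise Pearson
#' correlation about `r` within the block. Sparse columns zero out entries
#' with probability 0.5 (exact `0.0`, so zero-based selectors are
#' well-defined under floating point).
#'
#' @param config A [synth_config()].
#' @return A list with elements `table` (a [feature_table()]) and `manifest`
#'   (the [planted_truth()] data.frame).
#' @examples
#' out <- generate_feature_table(synth_config(n_pos = 10, n_neg = 10, p = 5,
#'                                            n_informative = 2, n_weak = 0,
#'                                            n_redundant_blocks = 0, seed = 1))
#' dim(out$table$values)
#' @export
generate_feature_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  if (config$n_pos < 2 || config$n_neg < 2) {
    stop_ctx("invalid synth_config: n_pos and n_neg must each be >= 2")
  }
  if (config$p < 1) stop_ctx("invalid synth_config: p must be >= 1")

  manifest <- planted_truth(config)
  n <- config$n_pos + config$n_neg
  p <- config$p
  labels <- rep(c("positive", "negative"), c(config$n_pos, config$n_neg))
  pos <- labels == "positive"

  values <- with_seed(config$seed, {
    baseline <- stats::runif(p, 1, 3)
    v <- matrix(stats::rnorm(n * p), n, p)
    v <- sweep(v, 2L, baseline, "+")
    shift <- numeric(p)
    shift[manifest$role == "informative"] <- config$effect_strong
    shift[manifest$role == "weak"] <- config$effect_weak
    shifted <- which(shift != 0)
    for (j in shifted) v[pos, j] <- v[pos, j] + shift[j]
    r <- config$within_block_corr
    if (config$n_redundant_blocks > 0 && config$block_size > 0) {
      for (b in seq_len(config$n_redundant_blocks)) {
        idx <- which(!is.na(manifest$block) & manifest$block == b)
        z <- stats::rnorm(n)
        for (j in idx) {
          v[, j] <- baseline[j] + sqrt(r) * z + sqrt(1 - r) * stats::rnorm(n)
        }
      }
    }
    sparse <- which(manifest$role == "sparse")
    for (j in sparse) {
      v[stats::runif(n) < 0.5, j] <- 0
    }
    v
  })

  tab <- feature_table(values, labels = labels,
                       sample_ids = paste0("s", seq_len(n)),
                       feature_names = manifest$feature,
                       provenance = "synthetic")
  list(table = tab, manifest = manifest)
}
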