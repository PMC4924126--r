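# Independent oracles and tiny fixture builders used across the suite.
# Oracles are deliberately written as plain, brute-force computations that
# share no code with the package internals they check.

# Shannon entropy (bits) by direct summation over observed frequencies.
oracle_entropy <- function(x) {
  tab <- table(x)
  p <- as.numeric(tab) / sum(tab)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Information gain by literal conditional-entropy expansion.
oracle_ig <- function(bins, labels) {
  h <- oracle_entropy(labels)
  n <- length(bins)
  hc <- 0
  for (v in unique(bins)) {
    sel <- bins == v
    hc <- hc + (sum(sel) / n) * oracle_entropy(labels[sel])
  }
  h - hc
}

# Confusion metrics by independent arithmetic.
oracle_metrics <- function(TP, FN, TN, FP) {
  se <- TP / (TP + FN)
  sp <- TN / (TN + FP)
  c(SE = se, SP = sp,
    ACC_pooled = (TP + TN) / (TP + FN + TN + FP),
    ACC_balanced = (se + sp) / 2)
}

# A small two-class table with hand-chosen values.
toy_table <- function(n_per_class = 10, p = 4, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  feature_table(x, rep(c("positive", "negative"), each = n_per_class),
                provenance = "toy")
}

# Linearly separable 2-feature toy: positives in the lower-left corner,
# negatives in the upper-right, margin comfortably over 1 after min-max
# normalization to [0,1]^2.
separable_toy <- function() {
  pos <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1), c(0.1, 0.1))
  neg <- rbind(c(1, 1), c(0.9, 1), c(1, 0.9), c(0.9, 0.9))
  feature_table(rbind(pos, neg),
                rep(c("positive", "negative"), each = 4),
                provenance = "separable")
}
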