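# mirsel

Feature selection impact on one-class versus two-class classification of
precursor microRNAs.

## The problem

Machine-learning detection of pre-miRNAs parameterizes candidate hairpins
with hundreds to >1,000 sequence/structure features and usually trains a
two-class classifier (TCC) against "pseudo hairpin" negatives. Genuine
negative examples do not exist, which makes one-class classification
(OCC) — learning from positives only and rejecting everything else as
*unknown* — an attractive alternative. But OCC lives or dies by its
feature set: noisy or redundant dimensions inflate the learned positive
region in ways no negatives can correct, while a margin-based TCC shrugs
most of them off.

`mirsel` packages the apparatus needed to study this interaction:

* **Eight filter selectors** producing ranked feature lists of size
  *m* = 50: highest/lowest information gain (HIG/LIG, with
  IG = H(Y) − Σ_v P(X=v) H(Y|X=v) on 10-bin equal-width discretized
  features), random selection (RFS), three selectors over a k-means
  clustering of the features themselves (k = 100): random member per
  cluster (RFC), centroid-closest members of size-ordered clusters (SFC),
  highest-IG member per cluster (HIC), plus a zero-norm selector on
  positive-class values (ZNF) and a Pearson-correlation redundancy filter
  (PCF). A consensus selection ranks features by frequency across
  per-dataset top-100 lists.
* **Two learners**: a k-means centroid one-class classifier (5 centroids,
  rejection radius = 0.95 quantile of training nearest-centroid
  distances, min-max-normalized space) and an RBF soft-margin SVM
  (K(u,v) = exp(−0.7·‖u−v‖²), C = 4, min-max normalization).
* **Monte-Carlo cross-validation**: repeated 90/10 splits — 100-fold for
  OCC with the full negative table injected as unknown class at test
  time, 10-fold stratified for TCC — reporting sensitivity, specificity,
  pooled and balanced accuracy with across-fold standard deviations, and
  a per-dataset `TCC_ACC − OCC_ACC` comparison table.
* **A synthetic generator** that plants informative, weakly informative,
  block-correlated (redundant) and zero-inflated features in Gaussian
  tables, with a ground-truth role manifest for every column.

## Worked example

Generate a table with 20 planted informative features (1.5 SD class
shift) among 300, select features by highest and lowest information gain,
and cross-validate both learners on each selection:

```r
library(mirsel)

out <- generate_feature_table(synth_config(
  n_pos = 200, n_neg = 200, p = 300, n_informative = 20, n_weak = 20,
  n_redundant_blocks = 10, block_size = 5, effect_strong = 1.5, seed = 1))
tab <- out$table
#> <feature_table> 400 samples x 300 features (200 positive, 200 negative) [synthetic]

cfg <- fs_config(m = 50, seed = 1)
hig <- select_hig(tab, cfg)
lig <- select_lig(tab, cfg)   # negative control: least informative features

positives <- ft_subset(tab, samples = tab$labels == "positive")
negatives <- ft_subset(tab, samples = tab$labels == "negative")
cv <- cv_config(folds_occ = 20, folds_tcc = 5, seed = 1)

mccv_occ(positives, negatives, hig, cv, occ_config())
#> <metric_summary> OCC/HIG/synthetic over 20 fold(s): SE=0.865 SP=0.963 ACC(bal)=0.914 ACC(pool)=0.954
mccv_occ(positives, negatives, lig, cv, occ_config())
#> <metric_summary> OCC/LIG/synthetic over 20 fold(s): SE=0.902 SP=0.081 ACC(bal)=0.492 ACC(pool)=0.155
mccv_tcc(tab, hig, cv, svm_config())
#> <metric_summary> TCC/HIG/synthetic over 5 fold(s): SE=1.000 SP=1.000 ACC(bal)=1.000 ACC(pool)=1.000
mccv_tcc(tab, lig, cv, svm_config())
#> <metric_summary> TCC/LIG/synthetic over 5 fold(s): SE=0.450 SP=0.390 ACC(bal)=0.420 ACC(pool)=0.420
```

With informative features both learners are accurate (OCC balanced
accuracy 0.914, TCC 1.000). Under the LIG negative control the one-class
model still accepts 90% of positives but its specificity collapses to
0.08 — the positive region learned from uninformative features swallows
nearly every negative — while the two-class model degrades to near-chance.
Balanced accuracy is the headline metric because every OCC fold tests
~10% of the positives against *all* negatives, so pooled accuracy is
negative-dominated.

The full study — seven simulated species datasets plus a shared 980-row
negative table, all eight methods, both learners, consensus selections,
comparison table and report — is one call:

```r
run_all(run_config(out_dir = "study", seed = 1))
```

## Documentation

The methods vignette
(`vignettes/feature-selection-occ-tcc.Rmd`) describes the model choices,
numerical conventions, the generator's scope and the known limitations.
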