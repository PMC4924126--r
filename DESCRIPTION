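Package: mirsel
Title: Feature Selection Impact on One- and Two-Class Pre-miRNA Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how feature selection affects one-class versus
    two-class classification of precursor microRNAs. Implements eight
    filter-style feature selection strategies (information-gain ranking,
    random selection, three feature-cluster-based selectors, a zero-norm
    selector and a Pearson-correlation redundancy filter) plus a
    cross-dataset consensus selection; a k-means centroid one-class
    classifier with distance-threshold rejection; a radial-basis-function
    soft-margin two-class classifier with min-max normalization; Monte-Carlo
    cross-validation with negative injection for the one-class protocol; and
    a synthetic feature-table generator with planted informative, redundant,
    weak and zero-inflated features for benchmarking the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
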