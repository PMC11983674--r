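Package: nmadissim
Title: Dissimilarity-Based Evaluation of the Transitivity Assumption in
    Network Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Empirical exploration of the transitivity assumption in network
    meta-analysis from study-level aggregate characteristics. Computes weighted
    Gower dissimilarities between studies over mixed-type characteristics
    (quantitative, binary, nominal, ordinal) with missing values handled by a
    co-observation indicator, aggregates them into within- and
    between-comparison root-mean-square dissimilarities, classifies the
    resulting comparison-by-comparison matrix against empirically derived
    thresholds of low dissimilarity, and applies hierarchical agglomerative
    clustering with cophenetic-correlation linkage selection and silhouette
    based partition selection to detect fragmented treatment comparisons.
    Includes a synthetic network generator with planted clustering structure
    and a reporting toolkit (classified heatmaps, dendrogram-heatmap
    combination, silhouette profiles, stacked bar plots of fragmented
    comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    pheatmap,
    stats,
    utils,
    grDevices,
    yaml
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
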