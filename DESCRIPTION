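Package: phnet
Title: Persistent-Homology Graph Filtration for Band-Power Connectivity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Threshold-free topological analysis of functional connectivity
    networks built from trial-by-region band-power matrices, as used in
    resting-state MEG studies. Converts each subject's power matrix into a
    Pearson correlation distance matrix, runs the graph filtration over all
    thresholds (beta-zero barcode, single-linkage dendrogram and ultrametric
    single-linkage matrix via a Kruskal minimum-spanning-tree sweep), and
    summarises global connectivity by the least-squares slope of the barcode
    within a component-count window. Group inference combines a two-sample
    t test on barcode slopes, a subject-relabelling permutation test on
    single-linkage distances, and Bonferroni-controlled Pearson correlations
    between edge distances and clinical covariates. A synthetic-cohort
    generator with planted attenuated-connectivity edges and coupled clinical
    covariates provides a ground-truth test bed for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
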