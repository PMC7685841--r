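Package: mhcprofiler
Title: MHC Expression Cluster Profiling of Molecular Cancer Subtypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies molecular cancer subtypes into MHC-low, MHC-intermediate
    and MHC-high expression clusters after suppressing immune-infiltrate
    confounding. Provides a synthetic multi-cancer cohort generator
    (negative-binomial RNA-seq counts with GC and batch effects, methylation
    betas as cell-type mixtures, nonsilent mutation tables), RNA-seq
    preprocessing (GC-stratified and between-sample quantile normalization,
    log2-CPM, PCA outlier removal, empirical-Bayes batch correction),
    reference-based methylation deconvolution by robust partial correlations,
    immune-correlation filtering of an immunomodulator panel, nonparametric
    relative-effect (rank-based ANOVA-type) statistics with permutation tests,
    and consensus clustering with validity-index rank aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    cluster,
    clue,
    stats,
    sva,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
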