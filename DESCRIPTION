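Package: psvnet
Title: Pseudo-Value Regression for Covariate-Adjusted Differential
    Co-Expression Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential co-expression network analysis of RNA-seq data
    with covariate adjustment. Gene association networks are estimated per
    condition by mutual information with ARACNE data-processing-inequality
    pruning, each gene's weighted degree centrality is converted into
    per-sample jackknife pseudo-values via leave-one-out network
    re-estimation, and the pseudo-values are regressed on the binary
    condition indicator plus clinical covariates with a robust MM
    estimator. Per-gene p-values are screened with an empirical Bayes
    adjustment (Benjamini-Hochberg available as an alternative) to call
    differentially connected genes. Includes a synthetic two-group data
    generator with known differentially connected hub genes for power and
    type-I-error evaluation.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    tools,
    parallel,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
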