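Package: vigorlink
Title: Linking Transcript Expression During Germination Sensu Stricto to
    Soybean Seed Vigor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for associating gene expression measured by qPCR during
    the first hours of seed imbibition with lot-level seed vigor. Implements
    relative quantification by the 2^-ddCt method with multiple reference
    genes and a pair-wise fixed-reallocation randomization test; Hill-curve
    fitting of cumulative germination time courses to extract t50; assembly
    of a vigor-trait matrix with Tukey compact-letter comparisons; Spearman
    co-expression networks; hierarchical clustering of expression variables
    by a first-principal-component homogeneity criterion; regularized
    canonical correlation analysis (ridge-penalized covariances) between
    gene clusters and vigor traits; and bootstrap distributions of the first
    canonical correlation used to rank gene clusters. A synthetic-data
    module emulates a two-cultivar, two-lot, three-timepoint study design
    with a latent vigor factor so the whole chain can be exercised without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
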