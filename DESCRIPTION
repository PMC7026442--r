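Package: diseasomix
Title: Exposure-Centred Diseasome Networks with Enrichment and Survival Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links an exposure transcriptome signature to cancer transcriptomes.
    Normalizes expression studies by per-gene Z-score, identifies up- and
    down-regulated genes with unpaired t-tests and log2 fold-change thresholds,
    builds direction-stratified bipartite gene-disease (diseasome) networks with
    Jaccard edge scores, performs Fisher-exact over-representation analysis
    against GMT gene-set libraries, and tests survival association of shared
    genes via Kaplan-Meier curves, log-rank tests, and Cox proportional-hazards
    models (univariate, multivariate, and combined with clinical covariates).
    Includes a synthetic-data generator with planted differential-expression
    overlap structure and proportional-hazards survival cohorts so that every
    stage of the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
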