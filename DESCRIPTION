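Package: lipidens
Title: Ensemble Biomarker Selection and Reverse-Causality Screening for
    Untargeted Lipidomics
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A case-control analysis pipeline for untargeted LC-MS
    lipidomics feature tables: reagent-blank and pooled-QC feature
    filtering, per-feature batch and gel-status adjustment by linear
    regression, upper-quantile scaling, ensemble variable selection
    intersecting a covariate-adjusted linear model, bootstrap-LASSO
    stability selection, and random-forest permutation importance,
    classification of selected features as potentially causal or reactive
    by regressing pair-level log fold-change on time to diagnosis, and
    supporting monoisotopic-mass and ppm annotation arithmetic.  Includes
    a synthetic matched-cohort generator with planted effects for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    Matrix,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
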