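Package: gpmnet
Title: Graph-Theoretical Predictive Modeling of Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts clinical symptom scores from weighted graph metrics of
    functional brain connectomes. Builds Fisher-z connectomes from node time
    series, computes integration, segregation and centrality measures on the
    positive-weighted graph, selects the single most symptom-associated metric
    inside each cross-validation fold, and fits covariate-adjusted linear
    models to predict held-out subjects. Includes a null-model comparison with
    the Nadeau-Bengio corrected repeated k-fold cross-validation t-test,
    permutation inference for prediction correlations, an elastic-net variant,
    the edge-based connectome-based predictive modeling (CPM) comparator, a
    unipolar-to-bipolar group-transfer mode, and a synthetic-cohort generator
    with planted, calibrated brain-symptom effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
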