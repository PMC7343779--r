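Package: cortexdti
Title: Cortical Grey-Matter Diffusivity Profiles and Diagnostic Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profile-based cortical grey-matter diffusion-tensor analysis.
    Fits the diffusion tensor to diffusion-weighted MRI, builds columnar
    cortical profiles through the grey-matter ribbon as streamlines of a
    Laplace potential between the white and pial boundaries, samples
    radiality metrics along them (AngleR, PerpPD, ParlPD, MD, FA),
    aggregates them to regional and whole-brain values, and runs the
    downstream statistics (multivariate GLM with covariates, one-way ANOVA
    with FDR-corrected pairwise post-hocs) and machine-learning protocol
    (PCA feature filtering, repeated ten-fold cross-validated classifier
    selection by majority vote, train/test evaluation with binary and
    multiclass performance metrics). Includes synthetic phantom and cohort
    generators so the whole pipeline is testable end to end without
    clinical imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    class,
    MASS,
    nnet,
    e1071,
    glmnet,
    randomForest,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
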