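Package: spectrait
Title: Trait Prediction and Elite-Genotype Classification from Canopy
    Spectral Reflectance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting wheat agronomic and physiological traits
    from canopy spectral reflectance (350-2500 nm) and for identifying elite
    genotypes by categorical modelling. Provides a declarative registry of
    spectral reflectance indices with linear trait screening; four
    multivariate regressors (principal component regression, partial least
    squares regression, ridge regression with a 100-value lambda grid, and
    epsilon-insensitive support vector regression with automatic kernel
    selection); range-based elite dichotomization with three classifiers
    (PCA-LDA, PLS-DA, and k-nearest neighbours); a 10-fold cross-validation
    harness reporting R-squared, RMSE, Willmott's Index of Agreement,
    accuracy, error rate, and per-class prediction rates; and a synthetic
    canopy-spectra generator (soil/vegetation endmember mixing with
    chlorophyll, water, and structure couplings) so every stage of the
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    class,
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
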