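Package: rqbso
Title: Ridge-Screened Q-Learning Bee Swarm Feature Selection for Clinical Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Wrapper feature selection for mixed-type clinical tables with
    missing values. Implements a cascade of hybrid k-nearest-neighbour
    imputation (weighted averaging for continuous variables, neighbour voting
    for discrete ones), z-score normalisation, closed-form ridge regression
    pre-screening, and a Q-learning-guided bee swarm optimisation search whose
    fitness is the cross-validated accuracy of a linear support vector
    machine. Includes a synthetic generator of clinical-like datasets with
    planted informative features so the whole pipeline can be exercised and
    validated without access to patient data.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    e1071,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
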