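Package: ooclassify
Title: Oocyte Competence Classification from Follicular-Cell Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates transcriptomic classifiers of oocyte
    competence from cumulus and mural granulosa cell microarray profiles.
    Implements leave-one-out cross-validation with univariate t-test feature
    selection performed strictly inside every fold, three classifier families
    (diagonal linear discriminant analysis, k-nearest neighbours, linear
    soft-margin support vector machines), logit calibration of predictive
    probabilities, permutation testing of the cross-validated error rate,
    ROC evaluation, and gene-symbol based translation of a signature to a
    second array platform with resolution of redundant probes. A synthetic
    expression-data generator with planted differential effects allows the
    whole pipeline to be exercised and tested without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
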