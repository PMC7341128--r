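Package: crosstrain
Title: Training-Set Composition for Cross-Population Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for studying how the
    composition of a genomic-selection training set affects prediction
    accuracy in structured diversity panels and in interspecific F2
    families. Simulates structured panels under the Balding-Nichols model,
    gametes and F2 families under Haldane (no-interference) meiosis on a
    genetic map, and quantitative traits with additive, dominance and
    epistatic quantitative trait nucleotides under five QTN-sharing
    scenarios with heritability-targeted noise. Fits ridge-regression BLUP
    (RR-BLUP) with restricted maximum likelihood variance components, a
    principal-component-only structure model, and genomic relationship
    (GBLUP) heritability; optimizes training sets by stochastic exchange
    maximization of the mean coefficient of determination of contrasts
    (CDmean); and evaluates Pearson prediction accuracy under replicated
    k-fold cross-validation, bootstrap resampling, and seven
    cross-population training configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
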