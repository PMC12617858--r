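Package: obscuredgp
Title: Obscured-Ensemble Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genomic prediction from pairwise genotype similarity. Implements
    the obscured-vector representation (a binary agreement vector between two
    genotypes), a small convolutional network that predicts one genotype's
    trait from the obscured vector plus a reference genotype's trait, and an
    ensemble predictor that averages pair predictions over a set of reference
    instances chosen at random or by training-set prediction accuracy. Includes
    marker-density tooling (sliding-window removal of identical markers,
    mutual-information ranking), ridge and GBLUP baselines on the VanRaden
    genomic relationship matrix, a leakage-safe cross-validation harness
    reporting Pearson correlation and mean squared error together, and a
    synthetic genotype/phenotype generator with linkage-disequilibrium blocks,
    planted duplicate markers and controllable heritability.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
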