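Package: pgscreen
Title: Quantitative Scoring of Pharmaco-Genetic Interaction Screens on
    Cultured Drosophila Follicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores in vitro follicle maturation screens run under
    cyclooxygenase (COX) inhibition. Computes per-replicate dumping
    fractions and dumping indices (aspirin over vehicle maturation),
    applies the wild-type quality-control band, normalizes each genotype
    against its within-experiment wild-type control, aggregates
    replicates, and classifies genotypes as enhancers or suppressors of
    COX-inhibition sensitivity using standard-deviation-derived bands.
    Ships the inferential tests used with such screens (one-way ANOVA,
    Dunnett many-to-one comparisons via the equicorrelated multivariate
    t, Welch and Student t-tests, each from raw replicates or summary
    statistics), a calibrated binomial screen simulator for end-to-end
    validation, and membrane-fluorescence quantification with cytoplasm
    background subtraction plus western-blot densitometry normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tiff,
    utils,
    withr,
    yaml
Suggests:
    multcomp,
    mvtnorm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
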