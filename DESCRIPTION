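Package: seaomega
Title: Median-Quadrant Association Analysis of Seafood Dietary Guidelines
    and Dietary Long-Chain Omega-3
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing country-level links between food-based
    dietary guidelines (FBDGs) for seafood and dietary long-chain omega-3
    (EPA+DHA) intake. Implements the median-quadrant (quadrate) association
    procedure: dichotomization of two country-level variables at their
    medians, 2x2 quadrant tabulation, an uncorrected Pearson chi-square
    test, association direction from quadrant concordance, and
    Bonferroni-protected significance across a family of comparisons.
    Also provides a four-attribute "positive attributes" country index
    compared across FBDG categories by one-way ANOVA, a species-weighted
    dietary EPA+DHA allocation model with weighted-mean imputation of
    unlisted consumption and proportional scaling to a recommended seafood
    intake, and a seeded synthetic-data generator (Gaussian copula on
    ranks) that emulates the covariate structure of compiled global
    country tables and skewed national seafood-consumption profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
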