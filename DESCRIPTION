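Package: rctfragility
Title: Fragility Index and Fragility Quotient Analysis for Two-Arm Randomized Controlled Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes the fragility index (FI) and fragility quotient (FQ) of
    statistically significant dichotomous outcomes from 1:1 two-arm randomized
    controlled trials, using an exact two-sided Fisher test (minimum-likelihood
    rule) recomputed after iterative event reclassification. Provides trial-corpus
    CSV input/output and validation, cohort-level descriptive statistics
    (median/IQR), nonparametric subgroup comparisons (Mann-Whitney U,
    Kruskal-Wallis), Spearman rank correlations of FI against trial
    characteristics, a seeded generator of synthetic significant-trial corpora for
    testing and simulation studies, and report writers producing plot-ready CSV
    and JSON artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
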