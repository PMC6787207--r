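Package: baitfate
Title: Bait-Fate Analysis of Scavenger Consumption at Wading-Bird Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the fates of monitored carcass baits placed
    in colonially breeding wading-bird colonies. Provides a seeded synthetic
    generator of camera-monitored bait deployment records, consumer and
    alligator size-class cross-tabulations with stratum proportions and
    relative risks, a from-scratch binomial logit mixed-effects model with
    site-nested-in-week random intercepts (Laplace approximation, with an
    adaptive Gauss-Hermite quadrature oracle for validation), AICc backward
    stepwise model selection, classical tests (Pearson chi-square, ANOVA,
    Spearman rank correlation), and a bioenergetic budget converting fallen
    nestling energy into the number of scavengers supported per breeding
    season.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    lme4,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
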