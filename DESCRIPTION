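Package: genetmle
Title: Targeted Semiparametric Estimation of Genetic Main and Interaction Effects
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Double-robust, semiparametric efficient estimation of average
    treatment effects and k-point average interaction effects (epistasis,
    gene-by-environment) of categorical treatments such as genotypes on
    continuous or binary traits under confounding. Implements plug-in,
    one-step (AIPW), targeted maximum likelihood (canonical and weighted
    fluctuation) estimators and their cross-validated versions with
    pluggable nuisance learners including a stacked cross-validated
    ensemble; efficient-influence-function based Wald inference, joint
    Hotelling tests, delta-method functions of estimands, positivity
    pruning and Benjamini-Hochberg adjustment for batch analyses; a
    sieve-plateau variance correction for genetic relatedness built on the
    genetic relationship matrix; and a parametric simulation harness with
    Monte-Carlo ground truth for coverage, bias and power evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    MASS,
    yaml,
    jsonlite,
    data.table,
    withr
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
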