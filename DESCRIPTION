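Package: prsproject
Title: Projected Predictive Accuracy of Polygenic and Environmental Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic projection of the predictive accuracy of polygenic risk
    scores, environmental risk scores, and their unweighted or least-squares
    weighted combinations, as a function of the GWAS training sample size and
    the P-value window used to select markers. Under a normal-null mixture
    model of marker effects and the liability-threshold model for binary
    disease, the package computes expected R-squared, area under the ROC curve,
    categorical and continuous net reclassification improvement, integrated
    discrimination improvement, sensitivity and specificity at absolute-risk
    thresholds, and the proportion of cases captured in top risk quantiles.
    Decision-support tools invert these quantities to find the optimal
    selection threshold and the training sample size required to reach a
    target accuracy, including a family-history parameterization for strongly
    heritable traits. A Monte-Carlo individual-level simulator generates
    cohorts under the same generative assumptions and serves as a brute-force
    check of every analytic formula.
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
    mvtnorm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
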