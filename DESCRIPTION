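Package: iccpool
Title: Bayesian Synthesis of Intracluster Correlation Coefficients for
    Cluster-Randomised Trial Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pools externally reported intracluster correlation coefficient
    (ICC) estimates for a planned cluster-randomised trial using a weighted
    Bayesian hierarchical logit-normal model fitted by a Metropolis-within-
    Gibbs sampler. Study- and outcome-level relevance weights can be derived
    from an expert panel by Rank-Sum importance weighting and linear opinion
    pooling, with Cronbach's alpha and inter-rater correlation diagnostics.
    The posterior ICC distribution feeds design-effect based power and
    sample-size calculations, including minimum-cluster-size searches over
    posterior quantiles. Includes Swiger's asymptotic ICC variance, classical
    multi-estimate comparators, and simulators with known ground truth for
    clustered outcomes, study tables and reviewer panels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
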