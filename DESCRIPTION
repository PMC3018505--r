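Package: profilereg
Title: Bayesian Profile Regression for Case-Control Studies with
    Categorical and Ordinal Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint Bayesian clustering of categorical and ordinal exposure
    profiles linked to a binary disease outcome. Subjects are partitioned by
    a truncated Dirichlet process mixture whose assignment submodel combines
    Dirichlet-multinomial likelihoods for nominal covariates with an
    ordered-threshold probit construction for ordinal covariates, while a
    disease submodel attaches a per-cluster risk (optionally a logistic
    baseline with confounder adjustment). Missing covariate entries are
    imputed stochastically inside the Gibbs sampler. Post-processing turns
    the posterior co-clustering structure into a similarity matrix, a
    deterministic best partition, per-group posterior risks, exceedance
    probabilities against the sample-average risk, and posterior odds ratios
    with credible intervals. A multifactor dimensionality reduction (MDR)
    comparator and a synthetic case-control data generator with planted
    cluster structure are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    Matrix,
    cluster,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
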