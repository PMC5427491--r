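Package: bpmtme
Title: Bayesian Poisson-Lognormal Multi-Trait Multi-Environment Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact Gibbs sampling for genomic-enabled prediction of count
    phenotypes measured on multiple traits in multiple environments, under a
    Bayesian Poisson-lognormal mixed model (BPMTME) with Kronecker-structured
    covariance priors for line, line-by-environment and observation-level
    effects. The Poisson likelihood is approximated by a negative binomial
    with a large size parameter whose logit form admits Polya-Gamma data
    augmentation, yielding closed-form Gaussian, inverse-Wishart and
    inverse-gamma full conditionals under a Huang-Wand prior hierarchy.
    Includes the univariate multi-environment special case (BPME), a
    model-based simulator, genomic relationship matrix construction from
    biallelic markers, and CV1 cross-validation with Spearman-correlation
    prediction-accuracy tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
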