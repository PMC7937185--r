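Package: antvar
Title: Multi-Level Behavioral Variance Analysis for Social Insect Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery and a reproducible workflow for analysing
    behavioral variation in ant colonies at three levels of social
    organisation: among colonies, among workers within colonies, and within
    workers (residual intraindividual variation). Implements a double
    hierarchical Gaussian mixed model (mean and log residual standard
    deviation submodels with correlated individual random intercepts) fitted
    by adaptive Metropolis-within-Gibbs MCMC, multivariate mixed models with
    among-colony, among-individual and residual correlation decomposition
    (behavioral syndromes), LMM-based repeatability (intraclass correlation)
    with parametric bootstrap intervals and randomization tests, and
    negative-binomial productivity regressions with information-criterion
    model selection. A hierarchical synthetic-data generator reproduces the
    study design end to end so every estimator is verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    glmmTMB
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
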