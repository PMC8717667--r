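Package: areaprev
Title: Bayesian Spatio-Temporal Mapping of Chronic Disease Prevalence from
    Administrative Health Records
Version: 0.1.0
Authors@R:
    person("areaprev", "maintainers", email = "areaprev@example.org",
           role = c("aut", "cre"))
Description: Tools for small-area analysis of chronic disease prevalence
    built from person-level administrative health records. Implements
    claims-based case-definition algorithms with censoring, construction of
    region by year by age-sex prevalence cubes, indirect age-sex
    standardization, socio-economic factor-index scores from census
    variables, and Bayesian hierarchical Poisson disease-mapping models:
    the Besag-York-Mollie (BYM) convolution model and spatio-temporal
    extensions with random-walk temporal priors and Kronecker-structured
    space-time interaction, fitted by Metropolis-within-Gibbs MCMC.
    Includes Moran's I permutation pre-tests, DIC/CPO/PIT model assessment,
    random-effect variance partitioning, posterior exceedance probabilities,
    and a fully synthetic data generator with known ground truth for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
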