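Package: hwblcm
Title: Bayesian Latent Class Models for Two Diagnostic Tests Without a Gold Standard
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hui-Walter Bayesian latent class estimation of diagnostic
    sensitivity, specificity and prevalence for two imperfect binary tests
    applied to two or more populations with no gold standard. Provides a
    data-augmentation Gibbs sampler for the conditional-independence model,
    a Metropolis-within-Gibbs sampler for the model with within-class
    covariance (conditional dependence) terms, Gelman-Rubin and effective
    sample size convergence diagnostics, credible-interval based model
    selection, positive and negative predictive values, prior sensitivity
    analysis, and a synthetic data generator emulating a two-population
    burnout screening study design (clinician-rated EDTB and self-reported
    OLBI instruments).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
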