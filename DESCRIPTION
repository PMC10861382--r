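Package: twinace
Title: One-Step Bayesian Twin Modelling of Ordinal Item Data with
    Genotype-Environment Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint estimation of an item response theory measurement model
    (generalized partial credit model for polytomous, ordinal questionnaire
    items) together with biometric ACE/AE/ADE variance decomposition for
    twin data, in which the unique-environmental variance may depend
    log-linearly on the latent genetic value (AxE/GxE interaction).
    Includes a synthetic twin-cohort generator, marginal maximum likelihood
    fitting of PCM/GPCM/GRM measurement models with AIC comparison and item
    information curves, a Metropolis-within-Gibbs sampler for the joint
    model with automatic imputation of missing item scores, deviance
    information criterion model comparison, highest posterior density
    intervals, Gelman-Rubin convergence diagnostics, and reporting of
    heritability and interaction effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
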