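Package: mtmebayes
Title: Bayesian Multi-Trait Multi-Environment Mixed Models for Breeding Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Bayesian multi-trait, multi-environment (MTME) linear mixed
    models to balanced randomized-complete-block breeding trials by Gibbs
    sampling with Gaussian and inverse-Wishart full conditionals. Provides
    model comparison by the deviance information criterion (DIC), Geweke
    convergence diagnostics, highest-posterior-density intervals, effective
    sample sizes, and posterior summaries of genetic parameters: broad-sense
    heritability, genetic correlations between traits, genotypic and residual
    coefficients of variation with the relative variation index, and genotype
    rankings by posterior-mean genetic value. Includes a synthetic-data
    generator for multi-environment trials with known ground truth, and a
    command-line workflow for simulation, fitting, and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    coda,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
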