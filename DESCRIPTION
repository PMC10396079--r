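Package: ncdilution
Title: Hierarchical Bayesian Organ-Specific Critical Nitrogen Dilution Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of organ-specific critical nitrogen dilution curves
    (Nc = A1 * W^-A2) for wheat leaf, stem and shoot biomass and leaf area
    index from multi-date nitrogen-rate trials, using a hierarchical Bayesian
    linear-plus-plateau model sampled by adaptive Metropolis-within-Gibbs
    MCMC. Includes posterior summaries with credible-interval uncertainty
    bands along the biomass axis, nitrogen nutrition index (NNI) diagnostics
    per organ basis with biomass-weighted combination, hybrid (pooled) curve
    fitting and agreement statistics (RMSE, normalized RMSE), coefficient of
    variation and significance grouping of curve parameters across
    genotype x environment x management conditions, growing-degree-day and
    trial covariate extraction with a Pearson correlation matrix, a synthetic
    trial generator with known ground-truth curves, and a deterministic
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    coda,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
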