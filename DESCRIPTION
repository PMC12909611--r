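Package: seajsdm
Title: Seascape Metrics and Latent-Factor Joint Species Distribution
    Models for Baited-Video Fish Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing demersal fish community counts from baited
    remote underwater video against the structure of the surrounding seascape.
    Derives patch-based covariates (substratum classification from fuzzy
    probability surfaces, distance to patch boundaries, windowed Shannon
    diversity of substrata, slope and aspect, distance to shore) from gridded
    rasters; fits a hierarchical Poisson joint species distribution model with
    species-specific covariate responses, site and year random intercepts and
    a low-rank latent-factor residual by adaptive Metropolis-within-Gibbs
    MCMC; and evaluates fits by WAIC-based stepwise selection, k-fold
    cross-validation, variance partitioning, credible-interval-screened
    residual species associations, and gridded abundance prediction. Includes
    a synthetic seascape and community generator with known ground truth so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    coda
Config/testthat/edition: 3
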