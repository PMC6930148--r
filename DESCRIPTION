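Package: jsdmnet
Title: Microbial Interaction Networks from Joint Species Distribution Model Residual Correlations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers putative microbial interaction networks from multi-group
    amplicon count tables along an environmental (successional) gradient.
    Count tables are rarefied, zero-imputed and centred-log-ratio transformed;
    plots are assigned to successional stages from the first principal
    component of environmental and vegetation variables; a hierarchical
    Bayesian Gaussian latent-variable joint species distribution model with
    environmental covariates and a spherical spatial correlation structure is
    fitted by Gibbs sampling; taxon pairs whose residual-correlation credible
    interval excludes zero become signed network edges; and network complexity
    (linkage density) is compared across stages. Includes a synthetic-data
    generator with planted latent-factor structure, and randomisation,
    richness-simulation, taxon-subsampling and gradient-standardisation
    robustness procedures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    vegan,
    picante,
    ape,
    coda,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
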