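# jsdmnet

Infers putative microbial interaction networks from multi-group amplicon
count tables sampled along an environmental gradient. Soil communities are
shaped both by species interactions and by shared environmental niches, and
raw co-occurrence networks confound the two. jsdmnet fits a hierarchical
Bayesian joint species distribution model (JSDM) that removes the effect of
measured environmental covariates and spatial autocorrelation, and builds
networks from what remains: the residual species-to-species correlations.

The package is aimed at microbial ecologists working with samples-by-taxa
count tables (16S, ITS, 18S, plant surveys) and per-sample environmental
metadata, who want networks of *interactions per se* rather than of shared
habitat preference, plus the machinery to show those networks are not
statistical artifacts.

## The model

For clr-transformed abundance `y_ij` of taxon `j` in plot `i`:

```
y_ij = beta0_j + x_i' beta_j + z_i' lambda_j + eps_ij,   eps_ij ~ N(0, sigma_j^2)
```

where `x_i` holds q z-scored environmental covariates (default: snow depth,
pH, soil moisture, CV of snow depth), `z_i` holds d latent-variable scores
(default d = 3) whose columns carry a spherical spatial correlation
`R(phi)` over plot coordinates, and `lambda_j` are taxon loadings. The
residual correlation between two taxa,

```
rho_jk = lambda_j'lambda_k / sqrt((||lambda_j||^2 + sigma_j^2)(||lambda_k||^2 + sigma_k^2)),
```

is the interaction proxy: a pair becomes a signed network edge when the 95%
posterior credible interval of `rho_jk` excludes zero. Network complexity
is summarised by linkage density (edges per node). Fitting is by a Gibbs
sampler (conjugate normal / inverse-gamma updates; random-walk Metropolis
for the spatial range), by default 40,000 iterations with burn-in 10,000
and thin 30, retaining 1000 draws.

Around the model, the package implements the full pipeline: per-group
rarefaction, count-zero-multiplicative zero imputation, per-group clr,
PCA-based successional-stage assignment, RDA with permutation tests,
alpha-diversity metrics (Chao1, Pielou's evenness, Faith's PD, rarity,
frequency), edge calling, network statistics, and four robustness
procedures (within-taxon randomisation, richness-effect simulation, taxon
subsampling, gradient-range standardisation). A synthetic-data module
generates surveys with known planted structure so everything is testable
without any deposited data.

## Worked example

```r
library(jsdmnet)

survey <- simulate_survey(
  n_samples = 30,
  groups = list(bacteria = list(richness = 40, depth = 1200),
                fungi    = list(richness = 20, depth = 600)),
  seed = 11)

cfg <- default_run_config()
cfg$rarefaction_depths <- c(bacteria = 1000, fungi = 500)
cfg$min_plots  <- 6         # core-taxon cutoff for 10-plot stages
cfg$iterations <- 2000; cfg$burn_in <- 500; cfg$thin <- 3
cfg$seed <- 11

res <- run_pipeline(cfg, survey$table, survey$metadata)
print(res)
```

```
[jsdmnet] rarefied: 30 samples x 60 taxa
[jsdmnet] PCA axis 1 explains 62.8% of covariate variance
[jsdmnet] covariates: snow_depth, pH, moisture, cv_snow
[jsdmnet] stage early: 10 plots, 52 modeled taxa, 9 edges (6.8 s)
[jsdmnet] stage mid: 10 plots, 55 modeled taxa, 23 edges (7.1 s)
[jsdmnet] stage late: 10 plots, 46 modeled taxa, 0 edges (7.9 s)
jsdmnet pipeline run
  early  nodes=7 edges=9 linkage density=1.3
  mid    nodes=14 edges=23 linkage density=1.6
  late   nodes=0 edges=0 linkage density=0.0
```

The PCA line reports how much of the covariate variance the successional
axis captures; each stage line reports the plots and core taxa entering the
model and the significant-edge count; the summary gives per-stage network
size and linkage density. Individual edges carry the posterior median and
credible interval of the residual correlation:

```r
head(res$stage_results$early$edges, 3)
```

```
  taxon_a taxon_b     median       lower      upper     sign
1  bac001  bac016 -0.8394061 -0.96778469 -0.2920757 negative
2  bac001  bac029  0.7157234  0.04065325  0.9771510 positive
3  bac001  bac039  0.8704888  0.31121274  0.9908323 positive
```

`write_network_outputs()` exports each network as an edge-list TSV, GraphML
(with group/trophic node attributes) and a statistics JSON.

The numbered scripts under `analysis/` walk the full study arc on a
simulated 75-plot survey: `01_simulate.R` (data), `02_preprocess.R`
(rarefaction + clr), `03_stages_ordination.R` (stages, RDA, diversity),
`04_fit_networks.R` (per-stage JSDMs and networks), `05_validation.R` (the
four robustness procedures). Each writes its tables under `results/`.

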