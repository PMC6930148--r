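---
title: "Inferring microbial interaction networks from residual correlations of a joint species distribution model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring microbial interaction networks from residual correlations of a joint species distribution model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jsdmnet)
options(jsdmnet.quiet = TRUE)
```

## The problem

Co-occurrence networks built directly from correlations of taxon abundances
confound two very different phenomena: genuine ecological interactions
(predation, facilitation, cross-feeding) and shared responses to the
environment (two taxa both preferring, say, low-pH soils co-occur without
ever interacting). jsdmnet separates the two with a hierarchical Bayesian
joint species distribution model (JSDM): measured environmental covariates
explain what they can of each taxon's abundance, a small number of latent
variables absorb the *residual* co-variation among taxa, and only the
correlations that remain after the environmental effects are removed are
interpreted as putative interactions. The package grew out of analyses of
multi-trophic soil communities (bacteria 16S, fungi ITS, small eukaryotes
and microfauna 18S, plus plants) sampled across a successional gradient,
where the question is how network complexity changes as succession
proceeds, but every step is generic.

## The model

Let $y_{ij}$ be the centred log-ratio (clr) transformed abundance of taxon
$j$ in plot $i$. The model is Gaussian in clr space:

$$y_{ij} = \beta_{0j} + \mathbf{x}_i^\top \boldsymbol\beta_j +
  \mathbf{z}_i^\top \boldsymbol\lambda_j + \varepsilon_{ij},
  \qquad \varepsilon_{ij} \sim N(0, \sigma_j^2),$$

with $\mathbf{x}_i$ the $q$ z-scored environmental covariates,
$\mathbf{z}_i$ the $d$ latent-variable scores of plot $i$ and
$\boldsymbol\lambda_j$ taxon $j$'s loadings. The residual covariance between
taxa $j$ and $k$ is $\boldsymbol\lambda_j^\top\boldsymbol\lambda_k +
1\{j=k\}\sigma_j^2$, so the residual correlation

$$\rho_{jk} = \frac{\boldsymbol\lambda_j^\top \boldsymbol\lambda_k}
  {\sqrt{(\lVert\boldsymbol\lambda_j\rVert^2 + \sigma_j^2)
         (\lVert\boldsymbol\lambda_k\rVert^2 + \sigma_k^2)}}$$

is the quantity of interest: the taxon-taxon association remaining after
the covariates' effects are removed. A pair becomes a network edge when the
95% equal-tailed credible interval of $\rho_{jk}$ excludes zero; the edge
weight is the posterior median and its sign the median's sign.

Spatial non-independence of nearby plots is handled by giving each latent
score column a spherical correlation structure over the plot coordinates,
$\mathbf{z}_{\cdot k} \sim N(\mathbf{0}, R(\phi))$ with
$R_{ii'} = 1 - 1.5\,h/\phi + 0.5\,(h/\phi)^3$ for distance $h \le \phi$ and
$0$ beyond the range $\phi$. Placing the structure on the latent columns
(rather than on a separate spatial row effect) means spatially structured
residual variation is absorbed by the same factors that generate the
residual correlations; the alternative row-effect formulation is a known
variant, and `fit_jsdm(coords = NULL)` drops the spatial structure
entirely.

### Sampling and priors

All conditionals are conjugate except the spatial range: intercepts,
covariate coefficients, loadings and latent scores take normal Gibbs
updates, residual variances inverse-gamma updates, and $\phi$ a random-walk
Metropolis step. Priors are deliberately vague, matching the conventions of
the JSDM package family: $\beta_{0j}, \beta_{jl}, \lambda_{jk} \sim
N(0, 10^2)$, $\sigma_j^2 \sim \mathrm{InvGamma}(0.01, 0.01)$, and $\phi \sim
\mathrm{Uniform}$ over the observed range of pairwise plot distances. The
loadings carry the standard factor-model identifiability constraint --
upper-triangular entries of the first $d$ rows fixed at zero, positive
diagonal -- which pins down the rotation; $\rho$ itself is
rotation-invariant, and a test checks that two independent chains agree on
the $\rho$ summaries to RMSE < 0.1.

Default chain settings are 40,000 iterations, burn-in 10,000, thinning 30,
retaining exactly 1000 draws. Convergence is monitored by Geweke z-scores
(first 10% vs last 50% of each chain, spectral variance estimates), and
model fit by standardised residuals -- for a Gaussian response the
randomized-quantile construction reduces to $(y-\hat\mu)/\hat\sigma$ --
summarised by the slope of the normal quantile plot. One caveat found
during development: with a Gaussian likelihood, heavy-tailed contamination
inflates $\hat\sigma_j$, so the QQ slope of contaminated data falls *below*
one (squeezed bulk, excess kurtosis in the tails) rather than above it; the
diagnostics report both the slope and the residual matrix so either
signature is visible.

## The pipeline around the model

`run_pipeline()` chains the standard preprocessing in the order the study
design requires:

1. **Rarefaction** per organism group to that group's even depth (defaults
   7987 / 1023 / 871 / 700 reads for bacteria / fungi / small eukaryotes /
   microfauna), subsampling without replacement; plots too shallow in any
   group are dropped everywhere.
2. **Stage assignment**: PCA of the z-scored environmental and vegetation
   variables; axis-1 scores, oriented so plant cover loads positively
   (late succession = high score), are split into three equal groups of
   plots (early / mid / late). Equal group sizes keep the number of modeled
   taxa and the statistical power comparable across stages.
3. **Core-taxon filter** per stage: only taxa present in at least 12 of the
   stage's 25 plots are modeled. The networks are therefore statements
   about *frequent* taxa.
4. **Zero imputation and clr**, per organism group: zeros are replaced by
   the count-zero multiplicative rule (a zero is treated as a value below
   the half-count rounding threshold, giving imputed proportion
   $0.65 \times 0.5 / n_i$ at depth $n_i$), non-zero parts are rescaled
   multiplicatively, and the clr transform is applied within each group --
   each group was rarefied to its own depth and so has its own
   compositional geometry; the clr matrices are then concatenated. Whether
   clr should instead be taken on the concatenated table is genuinely open;
   `clr_by_group(per_group = FALSE)` provides the alternative.
5. **Covariates**: the four defaults are snow depth, pH, soil moisture and
   CV of snow depth; when they are absent the pipeline falls back to greedy
   forward selection (`forward_select_env`), adding at each step the
   candidate that maximises the mean per-taxon least-squares R² of the
   environment-only model. "Explained the most variation" admits several
   formalisations; greedy mean-R² is the one implemented, and it is
   deterministic.
6. **Fit, edges, networks**: per stage, the JSDM is fitted, residual
   correlations summarised, edges called, and an igraph network built over
   the taxa incident to at least one edge. Excluding never-flagged modeled
   taxa from the node set is forced by the arithmetic of the reference
   complexity table (3481 edges / 209 nodes = 16.7 edges per node only if
   nodes counts network members, not all modeled taxa). Linkage density is
   reported with half-up rounding to one decimal.

## The synthetic-data generator

Real surveys of this kind cannot ship with a package, so every stage is
exercised against generators with known structure:

* `simulate_environment_spatial()` emulates the sampling design: a square
  grid at 50 m spacing with 10% jitter plus three 5 m clusters, and
  covariates sharing one dominant gradient so that PCA axis 1 explains a
  majority of their variance (the magnitude is tunable; 0 gives isotropic
  noise).
* `simulate_probabilities()` draws lognormal species-abundance
  distributions -- the standard parametric stand-in when observed relative
  abundances are unavailable -- and `simulate_dirichlet_multinomial()`
  turns them into overdispersed count tables (25 samples of 2000 reads in
  the validation settings).
* `sim_truth()` + `simulate_jsdm_community()` generate clr-space data from
  the model itself, with sparse planted loadings (a configurable fraction
  of taxa load $\pm\lambda$ on one factor; same-factor pairs then have
  residual correlation $\pm\lambda^2/(\lambda^2+\sigma^2)$, e.g. 0.69 at
  $\lambda = 1.5, \sigma = 1$). Generation is in clr space because that is
  the space the Gaussian model is fitted in; the Dirichlet-multinomial path
  is the count-space alternative.
* `simulate_survey()` composes the above into a full multi-group survey
  with environmental tilt plus planted cross-group latent factors in
  log-abundance space.

What the generators do *not* emulate: taxonomic structure, phylogenetic
signal in abundances, mechanistic (Lotka-Volterra) dynamics, and the exact
zero-inflation patterns of real amplicon data. Passing tests therefore show
the machinery is correct and calibrated, not that any particular real
community will yield dense networks.

## Verification strategy and observed operating characteristics

The test suite checks, among much else: the environment-only sampler
against per-taxon least squares (posterior means within Monte-Carlo error);
calibration on null clr data (with $n=25$, $p=40$, $d=3$, the proportion of
pairs whose 95% interval excludes zero is far below the 7% acceptance bound
-- typically well under 1%, i.e. the procedure is conservative); parameter
recovery on planted structure at $n=50$, $p=30$ (coefficient correlation
$\ge 0.9$, planted-edge sensitivity $> 0.7$); and the four robustness
procedures -- within-taxon randomisation (which preserves each taxon's
abundance multiset and occurrence frequency while destroying cross-taxon
association), richness-effect simulations (edge counts should not track
richness under the null generator), taxon subsampling, and
gradient-range standardisation (windows placed by sliding a fixed-width
interval over the sorted axis scores and keeping the leftmost placement
holding the most plots).

## Problem sizes and numerical choices

The shipped analyses and tests run at deliberately reduced scale: surveys
of 75 plots with ~240 taxa across four groups, per-stage fits of 25 plots
and 150-190 core taxa with chains of a few thousand iterations retaining
~1000 draws, and validation refits with shortened chains (a logged choice;
full-scale settings are one configuration line away). A per-stage fit at
this size takes about a minute on one core. Numerical details worth
knowing: the spherical correlation matrix carries a $10^{-8}$ diagonal
jitter for Cholesky stability; truncated-normal draws for the diagonal
loadings switch to a rejection sampler when the mean is far below zero;
rarefaction drops (and logs) samples below depth rather than erroring;
single-taxon groups (e.g. one plant) contribute an all-zero clr column,
which the variance-explained summaries exclude with a warning; stage
assignment breaks score ties lexicographically by sample id so it is
reproducible; and every seed-taking function restores the caller's RNG
state, so pipelines are reproducible end-to-end from one configuration
seed.

## Known limitations

Residual correlations are associations, not mechanisms: unmeasured
environmental gradients can masquerade as interactions, a caveat inherent
to the approach. The Gaussian-on-clr formulation requires imputing zeros
and will blur very sparse taxa (mitigated by the core-taxon filter). The
number of latent variables is fixed (three by default), not inferred. And
with $n = 25$ plots per stage, power to detect weak interactions is modest
-- the calibration results show the procedure errs on the conservative
side.
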