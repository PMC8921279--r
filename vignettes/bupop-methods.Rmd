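---
title: "Bottom-up population estimation with bupop: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bottom-up population estimation with bupop: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bupop)
```

## The estimation problem

In countries where the last census is decades old, up-to-date population
figures can be built *bottom-up*: enumerate a sample of small, well-defined
areas ("microcensus clusters", roughly three settled hectares each), link
the observed counts to geospatial covariates with complete coverage, and
predict population in all unsurveyed locations.  `bupop` implements such a
pipeline with building-footprint attributes as the covariate source: the
total footprint area in a location bounds where people can live, and
footprint morphology (building size, spacing, focal context) predicts how
densely they live there.

## The density model

For cluster $i$ with enumerated count $N_i$ and building-footprint area
$A_i$ (ha), the model is a hierarchical Poisson–lognormal regression of
population density $D_i$ (people per footprint hectare):

$$N_i \sim \mathrm{Poisson}(D_i A_i), \qquad
  D_i \sim \mathrm{LogNormal}(\bar D_i,\ \tau_{t,p}/\sqrt{v_i}),$$

$$\bar D_i = \alpha_{t,p,l} + \sum_k \beta_{k,t}\, x_{k,i},$$

with a random intercept nested by settlement type $t$ (urban/rural),
province $p$, and local area $l$; covariate effects $\beta_{k,t}$ by
settlement type, convertible to fixed effects $\beta_k$ when their
posteriors agree across types (`decide_effect_mode()`: the 95% credible
interval of the between-type contrast contains zero); and a density scale
$\tau_{t,p}$ per stratum.  Intercept means and effect means carry nested
normal hierarchies with diffuse hyperpriors; scales carry half-normal and
uniform hyperpriors.

**Weighted precision.** Household surveys often sample clusters with
probability proportional to a prior population estimate, which oversamples
dense places and biases a naive fit upward.  Each cluster's recorded
sampling weight $w_i$ (the selection weight) is truncated at its 90th
percentile (outlier control), imputed for randomly sampled rounds
(proportional rule: missing weights receive the observed mean, so rounds
contribute by cluster count; `impute_missing_weights()`), inverted and
normalized to model weights $v_i = w_i^{-1}/\sum_j w_j^{-1}$, and used to
scale each cluster's likelihood precision: the lognormal scale becomes
$\tau_{t,p}/\sqrt{v_i}$.  Oversampled clusters (large $w_i$, small $v_i$)
therefore carry less precision, which removes the preferential-sampling
bias in the same way an inverse-probability-weighted estimator does.

**Prediction.** Per-cluster precisions do not exist off-sample, so
predictions use a pooled stratum scale, the $\sqrt{v}$-weighted average of
the per-cluster scales (`pooled_precision()`), and propagate full
posterior-predictive uncertainty: per posterior draw, a density from the
lognormal layer and a count from the Poisson layer.  Cells with zero
footprint area are structurally zero.

A note on notation: sources in this literature sometimes call the second
lognormal argument a "precision".  `bupop` consistently treats it as the
standard deviation on the log scale (that is what the $\sqrt{1/(v_i
\tau^{-2})}$ form reduces to), and reads the diffuse `Normal(0, 1000)`
hyperpriors as variance 1000 (sd ≈ 31.6), the common convention in
Gibbs-sampler model files; both readings are configuration switches in
`model_config()`.

## Age–sex structure

Province-level counts in $G = 36$ groups (two sexes × 18 age bins: under 1,
1–4, five-year bins to 79, 80+) are modelled as Multinomial with a
conjugate Dirichlet prior with concentration $1/G$ per group.  The
posterior is Dirichlet$(1/G + \text{counts})$ in closed form, so
`fit_agesex()` samples it exactly — no MCMC — and `closed_form_summary()`
provides the analytic moments used as the test oracle.  Age–sex structure
is deliberately not offered below the province level: the smallest groups
would rest on a handful of individuals and produce spurious proportions.
Gridded group breakdowns multiply per-cell count draws by proportion draws
(`apply_agesex()`), aligning draws by index so both uncertainty sources
propagate.

## Sampling the posterior

`fit_density_model()` runs a Metropolis-within-Gibbs sampler written for
this model: conjugate Gibbs updates for every location-type parameter (the
latent-scale intercepts $\alpha$, hierarchy means $\xi$, effect means
$\rho$, and the coefficient block, drawn jointly from its multivariate
normal conditional) and adaptive random-walk Metropolis steps for the
latent log-densities and all scale parameters.  Latent densities are
explicit parameters, not marginalized, which keeps every conditional local
and cheap.  Proposal scales adapt toward standard acceptance targets during
burn-in only.  Defaults follow common practice for this model class: 3
chains × 10,000 iterations, burn-in 1,000, no thinning (the burn-in and
thinning values are this package's choices; they are not dictated by the
model).  Chains start from dispersed, data-informed points so the
Gelman-Rubin diagnostic (`gelman_rubin()`, classic between/within variance
ratio; convergence read as $\hat R < 1.1$) is meaningful.

The default monitored set is the prediction-relevant parameters: $\alpha$,
$\beta$, $\tau$, the pooled $\hat\tau$, and the stratum means $\xi_{t,p}$.
The deepest scale hyperparameters (e.g. $\sigma_t$ with its Uniform(0,
1000) prior and two effective observations) are deliberately excluded by
default: they are weakly identified by design, their wandering does not
affect predictions, and monitoring them would turn a diagnostic about the
quantities of scientific interest into a diagnostic about prior artifacts.
They can be added via `model_config(monitor = ...)`.

## The synthetic world

`generate_world()` / `draw_truth()` / `simulate_survey()` generate study
regions with known ground truth:

* a ~100 m cell grid with provinces as vertical strips and nested local
  areas, a smooth settlement-intensity field, and one guaranteed dense
  "town" per province (planted near the strip centre) so the morphological
  urban rule — a connected component (8-neighbour) with ≥ 40 footprint ha
  and ≥ 13 buildings — always produces both settlement classes;
* per-cell footprint summaries (area, count, mean building size, nearest-
  neighbour proximity, 2 km focal count) from transformed smooth Gaussian
  fields, with the three model covariates scaled by settled-cell grid
  mean/sd — the same constants applied to cluster summaries;
* clusters grown from seed cells over contiguous settled cells to ~3
  settled hectares (three cells), enumerated through the model's own
  layers; default truth values encode the field's stylized facts (rural
  densities near 450 people/footprint-ha and urban near 260, a strong
  negative mean-building-area effect, a rural-only proximity effect, a
  focal-count effect with opposite signs by type, log-scale sds around
  0.5);
* survey artifacts injected on demand: household nonresponse, undercounted
  clusters (thinned counts, flagged), clusters with zeroed footprint area,
  and heavy-tailed weight outliers — each exercising one preparation rule.

Two generator choices deserve explanation.  First, the cluster density
deviation is split between an i.i.d. part and a share of a smooth spatial
residual field (`residual_field_share`); marginally the deviation is
N$(0, \tau^2)$ either way, but only the field share makes
population-weighted *selection* genuinely informative about the deviation,
which is the phenomenon the weighted-precision approach corrects.  Recovery
experiments use share 0 (the exact model), design-effect experiments share
1.  Second, the selection proxy raises the cell population surface to a
power below one (`proxy_flatten`, default 0.6) before adding lognormal
noise: prior gridded population estimates used for real sampling frames are
shrunk relative to the truth, and an unflattened proxy would imply
implausibly dispersed weights.  Sampling fractions are kept small (about
300 clusters × 3 cells against ~5,600 settled cells): when a survey
enumerates most of a region, recorded selection weights no longer reflect
actual inclusion odds and *no* weighting scheme is consistent — an effect
easy to reproduce with the generator.

What passing tests on this world do **not** show: robustness to footprint
detection error correlated with density (clouds, canopy), non-residential
buildings, real settlement geometry, or manual cluster delineation — the
generator has none of these.

## Validation machinery

`crossvalidate()` refits the model $k$ times (default 10) with stratified
fold assignment — strata are never emptied from a training set where their
size allows; a single-cluster stratum falls back to the settlement-type
pool at prediction, logged — and predicts each held-out cluster once, with
weights renormalized within each training set.  `residual_metrics()`
reports bias (mean residual), imprecision (population standard deviation of
residuals, so that imprecision² + bias² equals the mean squared residual
exactly), inaccuracy (mean absolute residual), $R^2$, and 95%
prediction-interval coverage, plus scaled variants (residual/prediction).
$R^2$ defaults to the squared Pearson correlation of observed versus
posterior-mean predicted — the conventional reading — with the literal
correlation-of-residuals variant behind `r2_on = "residuals"`, because the
defining phrase in this literature is ambiguous.

Spatial structure in residuals is tested with Moran's I (row-standardized
inverse-distance weights among cluster centroids — the weight scheme is a
documented choice, configurable in principle — with a permutation p-value,
999 permutations by default, plus a permutation-moment normal
approximation) and an empirical semivariogram with pair counts per lag bin.

## Numerical choices and degenerate inputs

* Quantiles (weight truncation, interval bounds) use the linear
  interpolation convention (`stats::quantile` type 7).
* The 50 m household-constraint boundary is closed: a footprint at exactly
  50 m is kept.
* Half-normal distributions with nonzero location are normals truncated at
  zero with the location-dependent normalizing constant (`dhalfnorm`);
  inverse-CDF sampling makes the zero-scale limit degenerate at
  $\max(\mu, 0)$, which the zero-variance collapse tests rely on.
* `log_joint()` returns $-\infty$ outside the support rather than erroring,
  so samplers and optimizers can probe freely; a cluster with $A_i = 0$ and
  $N_i = 0$ contributes nothing, while $A_i = 0$ with $N_i > 0$ is
  impossible under the model and yields $-\infty$.
* Zero-variance covariates are rejected by `scale_covariates()` and
  excluded with a reason by `select_covariates()`; the screening threshold
  for collinearity is $|r| \ge 0.8$ (configurable — the level at which two
  footprint summaries typically duplicate each other).
* Empty prediction zones aggregate to zero with a warning; unseen local
  areas draw their intercept from the stratum level (logged), unseen strata
  from the settlement-type level.

## Problem sizes

The bundled experiments run at sizes a laptop handles comfortably: recovery
and convergence use ~300 clusters on a 150×150 grid with 3 chains × 4,000
iterations per fit (two seeded replicates in the routine suite; ten for the
full experiment), the design-effect comparison ten replicates of ~200
clusters with 2 × 2,000 iterations, and cross-validation examples a few
hundred clusters with short chains.  These sizes were chosen so the whole
suite exercises every code path at meaningful statistical resolution; all
of them scale up by changing the corresponding arguments.

## Known limitations

* The sampler is plain R; fits beyond a few thousand clusters or very long
  chains would benefit from a compiled likelihood.
* The model assumes counts and footprints are observed without error;
  measurement-error extensions are out of scope.
* Age–sex proportions are constant within provinces.
* The generator's geography (strip provinces, planted towns) is
  deliberately schematic; it exercises the estimator, not the cartography.
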