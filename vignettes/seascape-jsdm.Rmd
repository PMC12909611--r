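---
title: "Seascape joint species distribution modelling with seajsdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seascape joint species distribution modelling with seajsdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`seajsdm` models multi-species count data from baited-video surveys against
covariates describing the composition and configuration of the surrounding
seabed. This vignette is the package's account of the science it
implements: the model, the seascape covariates, the choices that were
genuinely open, and what the synthetic-data tests do and do not establish.

## The model

For deployment $i$ and species $j$, the observed MaxN count is modelled as

$$y_{ij} \sim \mathrm{Poisson}(\lambda_{ij}), \qquad
\log \lambda_{ij} = \alpha_j + \sum_k \beta_{kj} x_{ki}
 + \varepsilon^{S}_{ij} + \varepsilon^{Y}_{ij} + \mathbf{u}_i \cdot \mathbf{v}_j .$$

Every covariate effect is species-specific: a joint model is not a stack of
independent regressions but shares its random-effect and residual structure
across species. The site ($S$) and year ($Y$) terms are random intercepts,
drawn per level *and species* from $N(0, \sigma^2_S)$ and $N(0,
\sigma^2_Y)$ — the subscripts $ij$ matter: two species at the same site get
different intercept shifts, but a single SD per grouping controls them all.
The final term is a low-rank latent factor: each deployment carries an
unobserved score vector $\mathbf{u}_i \sim N(0, I_q)$ and each species a
loading vector $\mathbf{v}_j$. Marginally this induces a residual species
covariance $\Omega = V V^\top$ — co-occurrence beyond what the covariates
explain, whether from species interactions or from unmeasured environment.
$\Omega$ (and the correlation matrix derived from it) is invariant to
orthogonal rotation of the factors, which is why all reporting goes through
`residual_correlation_draws()` rather than the loadings themselves: the
loadings are not identified, the covariance is.

Assumptions worth stating: counts are conditionally Poisson (no separate
overdispersion term by default — the latent factor already absorbs
cross-species extra-Poisson variation; `model_spec(overdispersion = TRUE)`
adds a deployment-level normal residual if equidispersion given the factors
is implausible); deployments are conditionally independent given covariates
and random effects (a spatially structured random effect is deliberately
not implemented — `model_spec(spatial = ...)` raises an error — because
coordinate-based effects were evaluated and discarded in the survey design
this package follows); and covariate effects are log-linear.

### Priors

Fixed effects get independent $N(0, 10^4)$ priors — effectively flat on the
log scale. Each variance component (site, year, latent loadings) gets a
Gamma(0.1, 0.1) prior on its *precision*, the conjugate reading of a
"Gamma prior on the variance parameter"; this is identical to an
inverse-gamma(0.1, 0.1) prior on the variance itself. Both prior choices are
checked by tests: a prior-only run (likelihood disabled) must return
coefficient draws with SD $100 = \sqrt{10^4}$.

### Sampler

The posterior is explored by blocked Metropolis-within-Gibbs. The key
observation is that large parameter blocks are *conditionally independent*
and can be updated simultaneously with vectorised arithmetic:

- coefficients $\beta_{kj}$: for a fixed design column $k$, independent
  across species — one proposal vector per column, accepted per species.
  Only the rows where the column is non-zero enter the likelihood ratio
  (substratum dummies and their interactions are mostly zeros);
- random intercepts: level-by-species cells are fully independent;
- latent scores $u_{if}$: independent across deployments given loadings;
- loadings $v_{jf}$: independent across species given scores;
- precisions: exact conjugate Gamma draws.

Each scalar proposal is a Gaussian random walk with its own step size,
adapted in batches of 50 towards 44% acceptance during the first half of
burn-in and frozen afterwards, so every retained draw comes from a fixed
kernel. When the likelihood is disabled (`prior_only = TRUE`) every
conditional *is* its prior, and the sampler draws it exactly — still a
correct Gibbs step, not a shortcut. Chain seeds derive from the master seed
by fixed offsets, so runs are reproducible draw for draw and chains can be
re-run independently.

Convergence is monitored with rank-normalised split-$\hat R$ (constant
chains return 1 by convention; estimates fractionally below 1, pure noise
in the variance ratio, are floored at 1) and autocorrelation-based ESS with
Geyer's initial-positive-sequence truncation. Both calibrate correctly on
iid chains ($\hat R \le 1.05$, ESS within 20% of nominal) and on an AR(1)
chain with $\rho = 0.9$ (ESS within a factor 1.5 of $n(1-\rho)/(1+\rho)$).
Mixing of a random-walk sampler on a 20-column correlated design is
serviceable rather than spectacular; per-parameter ESS per chain is modest,
which is why default schedules run several chains and why interval-based
summaries (coverage, credible screening) are the primary inference outputs.

## Seascape covariates

The substratum input is *fuzzy*: one probability surface per class, with
overlapping support. Classification applies a per-class cutoff — 0.25 for
hard-edged rock and cobble/boulder, 0.1 for mud, muddy sand, sand and
gravel — so that the wide transition zones of soft sediments survive as
multi-label cells rather than being sliced by an arbitrary argmax. A cell's
dominant class is its highest-probability label.

**Patch boundaries.** A labelled cell is a boundary cell iff a
4-neighbour (edge-adjacent; diagonal-only contact does not create an edge)
has a different dominant class or an empty label set, *or* the cell itself
carries two or more labels — so fuzzy overlap zones register as boundary.
Cells outside the study area never create boundaries: the shoreline is a
physical boundary, not a patch boundary, and enters the model as its own
covariate (distance to shore). Boundary distance is planar Euclidean (m) to
the nearest boundary-cell centre; coordinates must be projected metres.

**Surrounding patch diversity.** $H = -\sum_c p_c \ln p_c$ (nats) of
dominant-class proportions among labelled, in-area cells whose centres fall
within a radius (500/1000/1500 m by default; cell membership is by
cell-centre inclusion, which keeps every value checkable by exhaustive
cell-counting). Circles clipped by the shoreline use only their in-area
part. Proportions use the hard dominant-class map rather than raw
probabilities: diversity "of the number and proportion of surrounding
substratum types" presupposes a classified map. A probability-weighted
variant is available (`weighted = TRUE`) but off by default. Note $H$ is
not monotone in circle radius in general — it is only guaranteed
non-increasing when shrinking onto a homogeneous core that already holds
the majority share.

**Terrain.** Slope (degrees) and downslope aspect (compass degrees) come
from Horn's 3×3 weighted differences on the depth surface. Missing
neighbours (grid edge, land) take the centre value — a zero-gradient
fallback that keeps nearshore cells defined. Flat cells have slope 0 and
*undefined* aspect (`NA`); the design matrix refuses `NA` covariates, so
deployments on flat cells must be dropped or imputed explicitly if aspect
is modelled. Aspect enters as a plain standardized covariate; its
circularity is ignored, acceptable for a term that model selection is
expected to discard.

**Depth strata.** Depths are positive-down metres, assigned to the six
design bands 0–9.9, 10–18.9, 19–29.9, 30–37.9, 38–49.9 and 50–116 m with
left-closed boundaries (9.9 → band 1, 10.0 → band 2, 116 → band 6; deeper
is outside the design and an error).

## Community assembly

Species observed in fewer than 10% of deployments within site-year groups
are removed before modelling. "Fewer than" is read strictly: the threshold
is `ceiling(fraction × group size)` and ties at exactly 10% are retained.
By default a species retained in *any* group is kept everywhere (a species
common anywhere is modelled everywhere); `mode = "all"` and an absolute
`min_occurrence` override cover the stricter readings, since the wording
"at each site each year" is genuinely ambiguous and published worked
numbers are not always consistent with a single rule. Sampling adequacy
uses the species accumulation curve: the permutation mean and its final
gradient (new species per additional sample), with the exact
hypergeometric expectation
$E[S_n] = \sum_j \left(1 - \binom{N-F_j}{n}/\binom{N}{n}\right)$ returned
alongside as a closed-form cross-check (and verified against vegan in the
test suite).

## Model evaluation

**WAIC** is computed cell-wise from draw-level Poisson log densities:
$\mathrm{WAIC} = -2(\mathrm{lppd} - p_\mathrm{waic})$, using online
log-sum-exp and Welford accumulation so thousands of draws never need to be
held in memory at once. **Stepwise selection** starts from the
intercept-only model and alternates add-best / drop-worst moves, forward
phase first; interactions are only entertained once their main effects are
present, and main effects are not droppable while a dependent interaction
remains. The acceptance threshold for a move is any WAIC decrease
(`min_delta = 0`, configurable). Two consequences are documented rather
than hidden: search-phase fits use reduced MCMC settings (WAIC ranking is
robust to shorter runs at these data sizes, and the selected model should
be refit at full settings), and with `min_delta = 0` a pure-noise covariate
is admitted in roughly a fifth of synthetic replicates — the familiar
behaviour of information criteria, which a positive `min_delta` trades
against sensitivity. **Radius selection** fits the single-covariate
diversity model at each radius with common random numbers (a paired
comparison, which also makes identical covariates an exact tie); ties go to
the smallest radius. **Collinearity** is screened by VIF; when two
covariates are collinear the package's rule keeps the one whose
single-covariate model has the better WAIC — the typical contest in fjordic
seascapes is depth against distance-to-shore, and this rule usually retains
depth.

**Cross-validation** partitions deployments into $k = 5$ seeded folds. A
held-out deployment is predicted by the posterior-mean intensity with its
site/year random-effect draws (levels are shared across folds) and the
latent term at its marginal expectation (score 0), because held-out
deployments have no identified score. The point prediction is the mean of
$\lambda$, not a count draw: RMSE against observed counts measures
predictive power of the intensity surface. RMSE is also reported as a
percentage of each species' observed MaxN range (to one decimal), the
scale-free form in which such results are usually quoted. A training fold
that happens to lack a substratum class leaves the affected held-out rows
unpredicted with a warning (they are excluded from that species' RMSE
denominator); missing site/year levels predict with the effect at zero.

**Variance partitioning** computes, per draw and species, the variance over
deployments of each covariate group's partial predictor $X_g \beta_g$ plus
the realized site, year and latent contributions, normalised to percentages
and averaged over draws. Percentages are non-negative and sum to 100 by
construction.

## Residual associations

Per draw, $\Omega = VV^\top$ is converted to a correlation matrix; a
species with zero loading norm in a draw is undefined for that draw and
dropped pairwise (counts logged). Pairs are screened by the equal-tailed
95% interval: supported iff both bounds share a sign. Equal-tailed rather
than HPD intervals were chosen because "interval overlaps zero" is a
quantile statement and quantiles are stable at moderate draw counts; at
least 40 draws are required for a 95% screen. Unsupported pairs are
rendered blank. On synthetic data with generative correlations $\pm 0.8$
(two factors — a rank-1 structure cannot represent intermediate
correlations) the screen recovers both signs in the large majority of
replicates with posterior means within 0.25 of truth, while fully
independent species show pairwise support well under 10%; that is error
*control*, not exact calibration, and is all that is claimed.

## Prediction

`predict_grid()` evaluates the posterior-mean intensity on every
predictable cell — in the study area, with a dominant class, with all
covariates defined — using the *same* metric operations as deployment
features, so training and prediction cannot drift apart. Random intercepts
are fixed at the requested conditioning levels (e.g. the best-sampled
year); the latent term is marginalised at score 0, since scores are
deployment-specific. Cells whose substratum class was absent from training
are masked and counted. Percent-area-present applies a presence rule to the
prediction raster; the default — Poisson occurrence probability at the
posterior-mean intensity, $1 - e^{-\hat\lambda} \ge 0.5$ — is one
defensible choice among several, so the rule used is always recorded on the
output. Response curves vary one covariate across its *observed* range
(extrapolation is refused unless forced), others fixed at observed means,
optionally one curve per substratum class.

## The synthetic seascape generator

The generator is first-class, tested code, and its defaults define the
study conditions every statistical claim is tested under:

- **Bathymetry**: a smooth field deepening away from a northern shoreline
  (offshore trend plus low-pass-filtered Gaussian noise), spanning 0–116 m
  so all six depth strata are populated; land cells (`NA`) give a real
  shoreline. Depth is stored positive-down.
- **Substratum**: six classes, each with a smooth spatial potential
  (smoothed noise at a 6-cell correlation scale plus an affinity for a
  class-typical depth). Per cell, each class's potential is compared
  against the best of the *other* classes through a logistic whose width is
  the class softness (0.8 for soft sediments, 0.25 for rock/cobble). The
  locally best one or two classes carry high probability, classes overlap
  near crossings, soft classes have measurably wider 0.1–0.9 transition
  zones than hard ones, and probabilities deliberately do not sum to 1 —
  the defining features of the fuzzy mapping product being emulated.
- **Design**: two sites (west/east halves) with up to three survey years,
  and an equal number of deployments drawn per depth stratum per site-year
  without replacement — the depth-stratified design contract, checked
  exactly.
- **Counts**: drawn from the model itself with user-supplied or
  plausible-default truth (intercepts around $\log 1.5$–$\log 2$, modest
  covariate effects, site/year SDs ≈ 0.25–0.3, mixed-sign loadings);
  random effects and scores are drawn fresh per replicate. The realized
  linear predictor, intensities and random draws are attached to the count
  matrix as ground truth.
- **Seeding**: one master seed expands into fixed per-stage substreams
  (bathymetry, substratum, deployments, counts), so stages can be re-run
  independently and everything is bit-reproducible.
- The raster default is 25 m cells (120 × 80 by default) — a free choice,
  as the emulated mapping product's resolution is not public.

What the generator does *not* emulate: real coastline geometry,
hydrodynamics or temperature, spatially autocorrelated residuals beyond the
latent factor, observer error in video substratum calls, and zero-inflation
beyond what Poisson-log-normal-like mixing produces. Passing tests
therefore establish internal correctness — the pipeline recovers what its
own model generates at survey-realistic sizes — not that the model is
adequate for any particular real seascape.

## Problem sizes and runtime choices

The test and acceptance computations run at desk scale, chosen once:
coefficient recovery uses 5 species × 300 deployments on the full
20-column design with one latent factor, 4 chains × 3000 iterations
(burn-in 1000), pooled over 20 replicates in the tests (≥ 85% coverage of
95% intervals required) and 8 replicates in the acceptance script;
association recovery uses 2-factor truths at $n = 300$ with 2 × 2000
chains; selection and cross-validation studies use 3 species × 150
deployments with single-chain search fits. The published-scale schedule —
8 chains × 30,000 iterations, 10,000 burn-in, thinning 10, giving 2000
retained draws per chain and 16,000 per model — is preserved in the
schedule arithmetic and is what `mcmc_settings()` accepts for a full-size
run.

## Known limitations

- No spatially structured random effect (by design; the stub errors).
- Random-walk Metropolis mixing limits practical model sizes to tens of
  species and a few hundred deployments; larger problems want a gradient
  or data-augmentation sampler.
- Factor loadings are reported only through rotation-invariant summaries;
  individual loadings are not interpretable.
- Aspect's circularity is ignored.
- Raster I/O is plain-text ASCII grid only; reprojection, resampling and
  geodesic distances are out of scope — inputs must share a projected
  metre grid.
- Residual associations are descriptive: a supported pair is co-occurrence
  beyond the covariates, never evidence of a direct ecological interaction.
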