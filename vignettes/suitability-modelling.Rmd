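---
title: "Environmental suitability modelling with suitscape: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Environmental suitability modelling with suitscape: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Mosquito surveillance programmes place baited traps across a region,
visit each location once during the season, and record the catch. The
modelling task is to turn those point observations into a map: an
*environmental suitability* score in $[0,1]$ for every 1-km² pixel,
expressing how favourable the local environment is for the species.
`suitscape` implements that workflow end to end — seasonal feature
extraction from monthly environmental rasters, occurrence preprocessing,
three suitability model families, mapping, and evaluation — together with
a synthetic landscape generator with a known truth model, so that every
stage can be validated without access to any proprietary survey data.

## Temporal Fourier features

Monthly remote-sensing signals (middle infra-red reflectance, day and
night land surface temperature, EVI and NDVI) are summarised per pixel by
temporal Fourier analysis into 14 components: the series mean `A0`, raw
minimum `MN` and maximum `MX`, the amplitudes `A1`–`A3` and phases
`P1`–`P3` of the annual, bi-annual and tri-annual cycles, the total
variance `VR`, the per-cycle variance proportions `D1`–`D3`, and their
sum `DA`.

For a series $x_t$, $t = 0,\dots,12Y-1$ covering $Y$ whole years, the
harmonic $k \in \{1,2,3\}$ (period $12/k$ months) is estimated by least
squares on $\cos$ and $\sin$ regressors at frequency $k$ cycles per
year. On a whole-years series these regressors are orthogonal, so the
least-squares fit coincides with the discrete Fourier transform, and the
intercept equals the arithmetic mean. From the coefficient pair $(a_k,
b_k)$,

$$A_k = \sqrt{a_k^2 + b_k^2}, \qquad
  P_k = \frac{12}{k}\,\frac{\operatorname{atan2}(b_k, a_k)}{2\pi}
  \ \bmod\ \frac{12}{k}.$$

Numerical and convention choices, all of which matter when comparing to
other TFA implementations:

* **Phases are months of peak**, in $[0, 12/k)$, not radians: `P1 = 6.5`
  means the annual cycle peaks in mid-July (counting January as month 0).
  To convert to radians multiply by $2\pi k/12$.
* **`VR` is the population variance** of the raw series (denominator
  $N$), and `Dk` uses the Parseval contribution $A_k^2/2$ of a sampled
  cosine, so that a noiseless sum of the three harmonics gives
  `D1 + D2 + D3 = 1` exactly.
* **`MN`/`MX` come from the raw series**, not the fitted curve.
* A constant series has `VR = 0`; all `Dk` and `DA` are then defined as 0.
* Series must cover whole years with no missing months; nodata pixels
  propagate nodata to all 14 components and must be masked upstream.

With 5 seasonal variables × 14 components plus the four static layers
(DEM, two precipitation products, population density) the standard
feature stack has 74 layers, named `<VAR>_<COMPONENT>`.

## Occurrence preprocessing

Catch counts are reclassified to presence/absence (≥ 1 individual =
presence) because each location is visited in a different week and
abundance varies seasonally while occurrence does not. Points are then
deduplicated to one record per 1-km² cell with presence priority: a
presence proves the cell suitable, an absence does not prove the
opposite. Ties within a class keep the lowest point id, which makes the
result independent of input order. Cells are half-open squares indexed
from the lower-left corner (`floor((coord − origin)/cell_size)`), fixed
so that placements are reproducible.

High-productivity agricultural land is never surveyed because it is
known to be unsuitable (no breeding sites). A model trained on trap data
alone therefore has no information about that class and can extrapolate
high suitability into it. `add_pseudo_absences()` places *probable
absences* uniformly at random in unoccupied excluded-class cells. The
count is configurable; the default, used when no count is given, is 5%
of the observed records — the appropriate number depends on the area of
the excluded class, and a published instance of this correction used 43
points for one province-scale region. Placement is assumed uniform; an
expert-chosen placement would be equally valid input.

## The three model families

All three families output a suitability in $[0,1]$ as the arithmetic
mean of balanced submodels; balance (equal presences and absences per
submodel) prevents the more prevalent class from biasing the score.

**Non-linear discriminant analysis (`method = "nlda"`).** Each of 100
balanced bootstrap samples (default $m = \min(\text{class sizes}, 150)$
per class) is clustered with k-means — presences and absences
separately, Euclidean distance on z-scored *generic variables* (DEM plus
the `A0, A1, A2, A3, MN, MX, VR, P1, P2, P3` components of MIR, day-LST,
night-LST and NDVI; 41 variables on the standard stack). Each cluster
becomes a Gaussian discriminant class with its own covariance and a
prior proportional to its size, and the suitability of a point is the
posterior probability of the presence super-class, computed with
log-sum-exp stabilisation. Design choices where the method description
is open:

* *Cluster count*: `k = 4` per class by default, configurable; clustering
  exists to capture heterogeneous habitat niches, and 4 sub-niches per
  class is a reasonable desk-scale default.
* *"LST" in the generic list* is read as both day and night LST.
* *Density space*: the discriminant densities live in the same
  generic-variable space as the clustering by default. Estimating a
  41-dimensional covariance from clusters of a 150-point bootstrap is
  already at the edge of feasibility; using the full 74-feature space
  would be worse. The covariance is regularised by $\lambda I$ with
  $\lambda = 10^{-6}\,\mathrm{tr}(\Sigma)/d$, escalated tenfold (up to
  $\mathrm{tr}(\Sigma)/d$) only if the Cholesky factorisation fails.
* *Phases are treated as linear* quantities in clustering and densities,
  not circular; with mid-latitude seasonal signals the phase
  distributions are far from the wrap point, but users comparing against
  other TFA stacks should be aware of the convention.
* *Per-submodel variable ranking* (for the importance table) is by the
  absolute standardised presence-vs-absence mean difference within the
  balanced sample; the method itself does not define a ranking, and this
  marginal separation score is simple and fast.

Because each cluster carries its own full covariance, small clusters fit
their bootstrap sample very closely and the posterior saturates near 0
or 1 at training points: NLDA training-set sensitivity and specificity
are typically ≈ 1 on the synthetic study. This is the known optimism of
internal validation amplified by a flexible density model, and it is the
reason the accuracy report prints the evaluation basis explicitly.

**Balanced-subset random forest (`method = "rf"`).** Five balanced
subsets are built by keeping the minority class whole and drawing an
equal-sized subset of the majority class without replacement. Each
subset trains a probability forest (500 trees by default,
`mtry = floor(sqrt(p))`, nodes grown to purity; implemented with
`ranger`), whose leaves hold presence fractions so tree output is
continuous. The final prediction is the plain average of the five
forests — the forests are *not* additionally bootstrapped, since each
tree already trains on a bootstrap. Importance is the mean decrease in
Gini impurity, averaged over the five forests.

**Balanced-bootstrap logistic regression (`method = "glm"`).** 100
balanced bootstrap samples each fit a binomial GLM by IRLS (relative
tolerance $10^{-8}$, ≤ 100 iterations) on z-scored features. An
unregularised logistic model is ill-posed when $p \approx n$, which the
74-feature stack reaches at bootstrap sizes, so two guards are explicit
and logged:

* a keep-first correlation screen (drop the later feature of any pair
  with $|r| > 0.95$, configurable) applied once before fitting;
* separation detection — IRLS non-convergence or any standardised
  coefficient beyond 15 in absolute value (odds ratios beyond $e^{15}$
  per SD are not plausible effects, only divergence) — triggering a
  lightly ridge-penalised fallback (`glmnet`, $\alpha = 0$,
  $\lambda = 10^{-4}$), flagged on the fit.

Variables are ranked by descending $|z|$ within each maximum-likelihood
fit and ranks averaged across fits; ridge-fallback fits carry no Wald
statistics and are excluded from the ranking (their count is reported).
If *every* submodel fell back to ridge, the importance method degrades
to ranking by absolute standardised coefficient, with a warning.

Spatial autocorrelation of the GLM residuals is checked with a Moran's I
correlogram: deviance residuals of the ensemble-mean prediction at the
training points, binary distance-band weights, 10 equal-width bins up to
half the maximum pairwise distance (beyond that the statistic is erratic
because few pairs remain). Bins with no pairs or zero residual variance
report `NA` rather than failing.

## Evaluation

Sensitivity (`TP/(TP+FN)`) and specificity (`TN/(TN+FP)`) are computed
on the training occurrence table at a configurable threshold (default
0.5, reported in the output). This is internal validation by design —
the goal is a suitability score describing the observed pattern — and
the resulting optimism is documented rather than hidden. Confidence
intervals are stratified percentile bootstrap: 2000 replicates, each
resampling presences and absences separately at their original sizes,
interval at the 2.5/97.5 percentiles. The percentile method is the
simplest consistent with stratified resampling; the method and replicate
count are recorded in the report.

## The synthetic study

`generate_landscape()` draws a patchy land-cover map (urban, sampled and
excluded agriculture, natural, water) by thresholding Gaussian-smoothed
white noise at the quantiles of the target class shares — the simplest
construction giving spatially autocorrelated classes with shares exact
up to ties. `generate_covariates()` builds each seasonal signal as
`mean + annual harmonic + bi-annual harmonic + white noise`, with the
mean and annual amplitude depending on land cover and on smooth
variable-specific random fields; static layers are a west–east DEM
gradient, two smooth precipitation fields, and population density high
in urban cells and zero on water. Defaults are temperate-climate
monthly-climatology scales (LST peaking in July, vegetation indices
peaking in early summer, higher in natural land than in built-up areas).

The truth model is logistic-linear on named derived features,
standardised over valid cells so coefficients are in SD units, with the
excluded agricultural class forced to zero suitability (it is defined as
unsuitable). `simulate_survey()` places traps uniformly within strata at
40/40/20 urban/agricultural/natural proportions (largest-remainder
rounding gives exact totals), one trap per cell, one visit per location
in weeks 1–30 (an April–October season); presence is Bernoulli with the
true suitability at the trap cell, and positive catches receive an
arbitrary positive count. The week and the count deliberately carry no
information once reclassified — mirroring why reclassification is done
at all. The abundance distribution is cosmetic by construction: only
presence/absence feeds the models.

What the generator does *not* emulate: real geography and climate
reanalysis, cloud-gap artefacts and irregular sampling in satellite
series, inter-species interactions, observation covariates (trap
efficiency, weather during the sampling week), and spatially structured
sampling bias beyond the stratified design. Passing tests on this
generator therefore demonstrates that the pipeline implements its stated
procedure correctly and recovers known structure under its assumptions —
not that any particular field dataset would be fitted well.

Two scenario configurations are used in the validation suite, chosen
once as part of the study design:

* the *default* configuration (50×50 km landscape, 3 years of monthly
  data, 300 traps, one species with three moderate drivers) for
  end-to-end runs; these sizes keep a full three-family run around ten
  seconds while leaving every class with hundreds of cells;
* a *recovery* configuration for driver-identification checks:
  land-cover-neutral seasonal parameters, fivefold month-to-month noise
  and doubled amplitude fields, so that the min/max/variance components
  become noise-dominated rather than shadows of the mean and amplitude.
  With the default, class-coupled parameters, a driver's correlated
  within-variable components legitimately share its importance and can
  crowd a top-10 list — the well-known dilution of importance measures
  under collinearity — which would test the feature correlation
  structure, not the ranking machinery. The recovery configuration makes
  "exactly three features drive suitability" true not just nominally but
  statistically.

## Reproducibility

Every stochastic stage takes a seed, and the pipeline fans a single
master seed out to per-stage, per-species and per-submodel child seeds
through a fixed integer mixing function (all below $2^{31}$). Reruns
under the same configuration are byte-identical across all artifacts,
which are plain text throughout: ESRI ASCII grids for rasters, CSV for
tables, YAML for configuration and the run manifest. Forests run on a
single thread so that tree growth is deterministic.

## Known limitations

* NLDA covariance estimation at $d = 41$ from 150-point bootstraps
  relies on ridge regularisation; its absolute suitability values are
  less calibrated than its ranking of locations (training accuracy
  saturates, see above).
* The GLM family inherits the ill-posedness of unregularised logistic
  regression at $p \approx n$; the screen/fallback machinery makes this
  explicit but a user wanting stable GLM coefficients should fit on a
  reduced feature set.
* Importance measures (all three families) are diluted by correlated
  features; the top-10 tables should be read as groups of related
  signals, not as a strict ordering of causal drivers.
* Evaluation is internal by design; reported sensitivity/specificity
  overestimate out-of-sample performance.
* Phases are linear, not circular, in clustering, densities and GLMs.
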