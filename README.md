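# suitscape

Species distribution modelling for trap-based mosquito surveillance:
from monthly environmental raster time series and one-visit trap surveys
to per-pixel **environmental suitability maps** in [0, 1], with three
model families, variable-importance tables and bootstrap-evaluated
accuracy.

Surveillance programmes for vector mosquitoes place baited traps across
a region (stratified, e.g. 40% urban / 40% agricultural / 20% natural),
visit each location once, and record the catch. `suitscape` turns such
data into suitability maps through the standard workflow:

1. **Temporal Fourier features** — each monthly signal (middle infra-red,
   day/night land surface temperature, EVI, NDVI) is summarised per
   pixel into 14 seasonality components: mean `A0`, min/max `MN`/`MX`,
   harmonic amplitudes `A1`–`A3` and phases `P1`–`P3` (annual, bi-annual,
   tri-annual; phases as month-of-peak), total variance `VR`, and
   variance proportions `D1`–`D3`, `DA`. For the harmonic *k* with
   least-squares cosine/sine coefficients (*a*, *b*):
   `Ak = sqrt(a² + b²)`, `Dk = (Ak²/2)/VR`.
2. **Occurrence preprocessing** — catches reclassified to
   presence/absence (≥ 1 individual = presence), one record per 1-km²
   cell with presence priority, and *pseudo-absences* added in excluded
   land cover that is known to be unsuitable and was never sampled.
3. **Three suitability ensembles**, each averaging balanced submodels:
   - `nlda`: non-linear discriminant analysis — k-means clusters of
     presences and absences on 41 generic seasonality variables, a
     Gaussian discriminant per cluster, suitability = posterior of the
     presence super-class; 100 balanced bootstraps.
   - `rf`: five balanced subsets (minority class kept whole), one
     probability forest per subset, averaged; Gini importance.
   - `glm`: 100 balanced bootstraps of a binomial GLM with |z|-based
     importance ranks and a Moran's I residual correlogram.
4. **Evaluation** — sensitivity and specificity on the training table
   with stratified percentile bootstrap CIs (2000 replicates, 95%).

Because real survey data of this kind are generally not public, the
package includes a first-class **synthetic study generator**: a patchy
land-cover landscape, seasonal covariates with known harmonic structure,
a known logistic truth model on derived features, and a stratified trap
survey — so the whole pipeline is testable against known ground truth.
See the methods vignette (`vignettes/suitability-modelling.Rmd`) for the
model details, parameter defaults and design decisions.

## Worked example

```r
library(suitscape)

# synthetic study region: 50 x 50 km, five land-cover classes
ls  <- generate_landscape(50, 50, seed = 1)
cov <- generate_covariates(ls, years = 3, seed = 2)

# 74-layer feature stack: 5 seasonal variables x 14 components + 4 static
features <- fourier_stack(cov)

# known truth: NDVI annual amplitude and day-LST mean attract the
# species, population density repels it (coefficients in SD units)
truth <- truth_model(c(NDVI_A1 = 1.5, DLST_A0 = 1.2, POPDEN = -1))
suit  <- true_suitability(truth, features, ls)

# stratified one-visit survey, then the occurrence table
survey <- simulate_survey(ls, n_traps = 300, seed = 3, suitability = suit)
pts <- dedup_cells(survey_to_points(survey), ls)
pts <- add_pseudo_absences(pts, ls, seed = 4)   # default: 5% of records
occ <- extract_features(pts, features)
table(occ$presence, occ$origin)
#>     observed pseudo_absence
#>   0      171             15
#>   1      129              0

fit <- suitability_ensemble(presence ~ ., occ, method = "rf", seed = 5)
fit
#> <suitability ensemble: rf> 5 submodel(s), m = 129
#>   training data: 129 presences, 186 absences; 74 features

map <- predict_grid(fit, features)   # suitability raster, [0, 1]
map
#> <env_grid> 50 x 50 cells, cell size 1, origin (0, 0)
#>   values: [0.0236, 0.9716], 0 nodata

head(as.data.frame(top_importance(importance(fit))), 5)
#>   variable    score n_submodels
#> 1  NDVI_DA 5.532320           5
#> 2  NDVI_VR 5.464996           5
#> 3  NDVI_A1 4.740002           5
#> 4  NDVI_D1 4.699484           5
#> 5   EVI_MX 4.052012           5

accuracy_report(list(species_a = list(rf = fit)), seed = 6)
#> Accuracy (training data, stratified percentile bootstrap CIs)
#>    species model      metric               value
#>  species_a    rf sensitivity 1.000 (1.000-1.000)
#>  species_a    rf specificity 0.968 (0.941-0.989)
```

The importance table reads as expected: NDVI seasonality components —
the annual amplitude `NDVI_A1` and its correlated shadows `NDVI_DA`,
`NDVI_VR`, `NDVI_D1` — dominate, because correlated components of a true
driver legitimately share its importance. `m = 129` is the minority
class size: each of the five forest subsets pairs all 129 presences with
129 absences drawn without replacement. The accuracy is internal
(training-data) validation by design and is therefore optimistic; the
report says so in its header.

The full pipeline (all three families, maps, importance tables, accuracy
CSV, correlogram, manifest — all plain-text artifacts, byte-identical
under a fixed seed) runs from one configuration object:

```r
run <- run_pipeline(default_run_config(seed = 1), out_dir = "run1")
```

or from the shell via the thin CLI wrapper:

```sh
Rscript inst/cli/suitscape.R all --out run1 --seed 1
Rscript inst/cli/suitscape.R ablate --seed 1   # pseudo-absence contrast
```

The `ablate` command runs the pipeline twice, identical except for the
pseudo-absences (0 vs *n*), and reports the mean predicted suitability
over the excluded land-cover cells in each run — the correction's effect
is that predictions over known-unsuitable land drop substantially.

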