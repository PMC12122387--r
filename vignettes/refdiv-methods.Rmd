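---
title: "Methods: quantifying marine-reference sensitivity of freshwater divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying marine-reference sensitivity of freshwater divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refdiv)
```

## The problem

Studies of rapid freshwater adaptation in threespine stickleback routinely
use a contemporary marine population as a proxy for the ancestral state, and
measure freshwater evolution as the displacement of each lake population
from that marine reference in a morphometric trait space. This rests on the
assumption that marine populations are phenotypically homogeneous, so that
the choice of marine sampling site is immaterial. `refdiv` implements the
machinery needed to test that assumption: it estimates (i) the magnitude of
marine-freshwater divergence per (reference, lake) pair, (ii) the
parallelism of freshwater trajectories sharing a reference, and (iii) how
much both quantities move when the reference is substituted, together with
geographic and environmental predictors of that movement.

## Trait model and size correction

Ten traits are analysed in a fixed, documented order (see
`stickleback_traits()`): eight linear measurements in mm (body depth,
pelvic spine and girdle lengths, two dorsal spine lengths, mouth width, eye
diameter, caudal peduncle depth) and two counts (lateral plates, gill
rakers).

Linear traits scale with body size, so raw values are corrected to a common
standard length before any multivariate analysis:

$$\gamma_i = \chi_i - \beta\,(L_i - \bar{L}),$$

where $\chi_i$ is the raw trait value of fish $i$, $L_i$ its standard
length, $\bar{L}$ the grand mean standard length of the whole dataset, and
$\beta$ the ordinary least-squares slope of the trait on length. Slopes are
fitted separately per trait and population by default
(`grouping = "per_population"`), because allometric slopes commonly differ
among populations; a pooled common slope is available. $\bar{L}$ is always
the single dataset-wide average — the correction recentres every fish to
one shared body size, so per-group centring would defeat its purpose.

Two exemptions follow standard practice for meristic traits that do not
grow with the body: gill raker number is never corrected, and lateral plate
number is left uncorrected in marine fish. Plates in freshwater fish *are*
corrected under the default settings; this asymmetry is deliberate (plate
number varies strongly in freshwater fish and shows a residual association
with size there), but it is biologically debatable, so
`exempt_plates_globally = TRUE` switches it off and the choice is recorded
in the audit log. Missing trait values propagate as `NA`; nothing is
imputed.

Correction is idempotent in effect: refitting the allometry on corrected
values returns slopes below $10^{-8}$, which the test suite asserts.

Within-habitat variance homogeneity is screened with the
Brown–Forsythe/Levene test (`levene_test()`, delegating to `car`): a
one-way ANOVA on absolute deviations from the group centre. The default
centre is the group median — the conventional, outlier-robust choice and
the default of the implementation this field typically uses — with mean
centring available; the choice is recorded in the result object.

## Morphospace, divergence vectors and theta

`run_pca()` performs PCA on the correlation matrix by default: the traits
mix millimetres and counts with variances two orders of magnitude apart, so
covariance-matrix PCA (available via `scale = FALSE`) would be dominated by
the plate count. Two determinism conventions are applied: the
largest-magnitude loading of every axis is made positive, and
`orient_to_habitat()` optionally reflects PC1 so that freshwater centroids
score higher than marine ones. Both are reflections; angles and distances
are unaffected.

Site centroids are per-site means of specimen scores. Two divergence
metrics are computed per (marine reference, freshwater site) pair:

* the absolute PC1 centroid difference (`axis_divergence()`), a
  single-axis composite of the armour/body-depth contrast; and
* the Euclidean norm $L$ of the divergence vector
  (`divergence_vector()`), computed by default over **all** PC axes. Using
  the full rotation makes $L$ and all angles identical to their values in
  the z-scored trait space (the rotation is orthogonal), so nothing hinges
  on how many axes are "kept". A truncated axis set can be requested and is
  recorded in the output; with a single axis, $L$ reduces exactly to the
  axis divergence.

Parallelism of two freshwater populations diverging from the same reference
is the angle between their divergence vectors:

$$\theta = \arccos\!\left(\frac{v_1 \cdot v_2}{\lVert v_1\rVert\,\lVert v_2\rVert}\right),$$

reported in degrees. The cosine is clamped to $[-1, 1]$ before the arccos,
so `theta(v, v)` is exactly 0. Small angles indicate parallel evolution;
90° is the null expectation for unrelated directions. A zero-length vector
has no direction, and asking for its angle is an error — silently returning
0 would fabricate perfect parallelism. For $k$ freshwater sites,
`theta_set()` returns $\binom{k}{2}$ records per reference (15 for six
lakes, 150 across ten references).

The panmictic reference pools every marine fish into one nominal site
(`pool_panmictic()`). The pipeline implements this by relabelling sites in
the *same* fitted PCA rather than refitting, so panmictic and
per-reference analyses share one morphospace; the pooled centroid is then
exactly the sample-size-weighted mean of the marine site centroids.

## Mixed models

`fit_lmm()` fits Gaussian models by REML through `lme4`, with a single
optional random intercept; without one the fit reduces to ordinary least
squares (the test suite checks the collapse at the $\tau^2 = 0$ boundary to
$10^{-6}$). Three conventions need stating because the reported statistics
depend on them:

* **Denominator df.** Fixed effects are tested with the classical
  between-within rule for a two-level design: a predictor varying within
  groups is tested against $n - g - p$ df ($n$ observations, $g$ groups,
  $p$ non-intercept fixed columns). This is documented in every output.
* **Variance-component SE.** The random-intercept variance is reported with
  a standard error from the curvature (finite-difference Hessian) of the
  restricted log-likelihood, evaluated at the REML estimates in the
  $(\tau^2, \sigma^2)$ parametrisation. The likelihood is computed
  independently of `lme4` from the marginal covariance
  $V = \sigma^2 I + \tau^2 Z Z^\top$. At a boundary estimate the Hessian is
  not positive definite and the SE is reported as `NA` rather than a
  made-up number. A simulation test checks that the reported SE tracks the
  empirical spread of the estimator.
* **Convergence.** Optimiser complaints are captured into the fit object
  (`converged`, `messages`) instead of escaping as warnings; they are
  printed with the fit. p-values are reported but never drive control flow.

`reference_effect_test()` fits
`divergence ~ reference + (1 | freshwater site)` and reports the reference
sum of squares and F (numerator df = references − 1). Two subtleties:

* **Degenerate residuals.** When every freshwater centroid exceeds every
  marine centroid on PC1, $|\Delta\text{PC1}|$ is *exactly* additive in
  (lake, reference): the residual variance is numerically zero and the F
  statistic is astronomically large and meaningless in magnitude (though
  its message — the reference matters — is correct). The fit is flagged,
  and the vector-length and theta reference tests, whose responses are not
  additive, provide finite F statistics.
* **The permutation null.** The optional calibration permutes reference
  labels within each lake, i.e., it tests exchangeability of divergence
  values across references within lakes. Note what is *not* null in this
  sense: divergence tables computed against a shared set of sampled marine
  centroids, even when all marine population means are equal. The sampling
  error of each marine centroid enters every divergence involving that
  reference and is therefore a *realized* reference effect, which the test
  correctly detects. This is the finite-sample face of the package's core
  point: any particular marine sample imprints itself on every divergence
  estimate made against it. The type-I calibration in the test suite
  accordingly simulates the exchangeable null directly (lake effects plus
  independent noise) and confirms the 5% level over 200 replicate tables.
  For speed, the permutation inner loop recomputes F via the sequential
  two-way ANOVA (lake, then reference), which equals the mixed-model F in
  balanced layouts — an identity the suite asserts at $10^{-6}$.

`percent_change_by_reference()` summarises reference sensitivity per lake
as $100 (\max - \min)/\max$ over its per-reference divergences. Max
normalisation is the default because it is bounded by 100% and reads as
"switching references can shrink the estimate by up to X%"; min and mean
normalisations are available and recorded.

## Geography and climate

Shortest waterway distance is computed on a water/land raster in a
projected km plane (`lonlat_to_km()`, equirectangular — adequate over a few
hundred km). The water lattice is 8-connected with diagonal steps costing
$\sqrt{2}\times$ cell size; 4-connectivity, which overestimates diagonal
channels by ~41%, is available as an option. Shortest paths are Dijkstra's
algorithm via `igraph`, validated in the tests against exhaustive
enumeration of simple paths on small grids. Shoreline sites snap to the
nearest water cell within 3 cells by default (logged); points with no
water inside the radius, and pairs in disconnected water bodies, are
errors rather than sentinel values. Grid distances carry a discretisation
error bounded by the $\sqrt 2$ factor; halving the cell size never
lengthens a path beyond that bound.

Climate enters as 19 bioclim-style site variables. Collinearity is pruned
greedily at $|r| > 0.80$ in a documented priority order that prefers
annual-trend and overall-variation variables (BIO01, BIO12, BIO02, BIO03,
BIO15, BIO08, then the remaining codes ascending); the walk is
deterministic and invariant to site order, and constant variables (with
undefined correlations) are dropped with a warning. The retained variables
feed a correlation-matrix PCA (units mix °C, mm and percentages), and the
environmental difference of a site pair is the absolute difference of
their scores per axis.

Distance-decay models regress PC1 divergence on waterway distance or
environmental difference with lake as a random intercept; marine-only
models (pairwise marine-marine morphological distances) are ordinary
regressions, since each marine site appears in many pairs but there is no
natural grouping factor analogous to the lake.

## The synthetic generator

`generate_specimens()` draws from a hierarchical Gaussian model with
linear allometry:

* **Site level.** Each site's trait mean is the habitat baseline plus a
  spatially autocorrelated among-site deviation: a Gaussian field with
  exponential correlation $\exp(-d/\text{range})$, range 120 km by default
  at a ~300 km study extent. Spatial autocorrelation is what makes nearby
  marine references give similar divergence estimates and distant ones
  different — the distance-decay structure the analysis is designed to
  detect. Freshwater sites additionally receive a shared offset
  (`parallel_effect`, the direction of parallel evolution: deeper bodies,
  fewer plates, shorter spines, fewer rakers) plus a site-specific
  deviation (`nonparallel_sd`, or an explicit offset matrix for
  constructed geometries).
* **Fish level.** Standard length is Gaussian (mean 50.71 mm, SD 6 mm);
  each trait is the site mean plus `slope × (length − mean length)` plus
  independent Gaussian noise. Counts are rounded to the nearest
  non-negative integer rather than drawn from a Poisson, so that the
  configured variances are honoured — within-habitat trait variances are
  the quantity the variance screen works with, and the defaults use
  realistic habitat-specific values (e.g., body depth variance 0.26 in
  both habitats; plate variance 0.02 in marine fish, which are nearly
  uniformly fully plated, against 1.02 in freshwater fish).

The default design is 10 marine and 6 freshwater sites on approximate
coastal British Columbia coordinates with 20-60 fish per site. The
among-site SD defaults to 0.8× the within-site SD per trait, and the
non-parallel SD to 0.8× the freshwater within-site SD: one fixed choice
that yields the qualitative regime of interest — a strong reference effect,
mean theta in the tens of degrees with clear spread across references, and
per-lake percent changes of roughly 15-40%.

Every run returns a ground-truth record: realized site means, the true
per-lake divergence directions, and the pairwise angles implied by the
configured offsets (measured in marine-SD-standardised trait space, the
scale the correlation PCA effectively works on). With `nonparallel_sd = 0`
the expected angles are exactly 0; offsets placed on distinct traits are
exactly orthogonal and survive per-trait rescaling.

**What the generator does not emulate.** Measurement and scorer error
(traits are drawn noise-free around their regression line beyond the
residual SD); genetic structure or temporal change; bounded or skewed
trait distributions; and marine-specific drivers such as salinity — in the
synthetic world, marine-marine similarity decays with distance exactly as
marine-freshwater similarity does, whereas field data need not behave that
way. One quantitative limit is worth knowing: because the correlation PCA
z-scores each trait by its *total* SD, pumping up among-site variance also
inflates the denominator, so across-population score variances saturate
well below what a covariance-scale analysis of field data can show.
Passing parameter-recovery tests therefore demonstrates that the
estimators recover known geometry under the model's assumptions, not that
field data meet those assumptions.

## Reproducibility and numerical conventions

A pipeline run (`run_pipeline()`) forks its seed once per stochastic
module, so module-level reruns are independently reproducible; re-running
an identical configuration reproduces every output byte-for-byte (floating
outputs are written at 12 significant digits to make that meaningful). Any
stage failure aborts with the stage name. The run manifest records the
seed, forked module seeds, settings, and package and R versions.

Problem sizes used by the test suite and acceptance script were chosen to
keep the whole suite in the order of a minute on one core: parameter
recovery uses the full 16-site design at 60 fish per site over 10-20
seeds; the type-I calibration uses 200 null tables with 199 permutations
each; variance-component recovery uses 50 replicates of a 6-group × 10
design. The same estimates at larger sizes only sharpen; none of the
assertions sits near its tolerance.

## Known limitations

* Exact reproduction of mixed-model F statistics across software depends
  on the denominator-df convention and estimation details; the
  between-within convention used here is stated in every output but is not
  the only defensible choice.
* The reference-effect F on a single PC axis is uninformative in magnitude
  whenever habitats separate completely (see above); use the vector-length
  or theta versions for an interpretable F.
* Waterway distances inherit raster discretisation error (≤ √2) and the
  equirectangular projection's distortion, which grows beyond a few
  hundred km.
* The permutation calibration treats the divergence table as the unit of
  analysis; it does not propagate specimen-level sampling error of the
  centroids. A full specimen-level resampling scheme (e.g., bootstrapping
  fish within sites) would be the natural extension.
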