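# refdiv

Quantifying how the choice of a marine reference population changes
inferred patterns of freshwater divergence and parallelism in threespine
stickleback morphometrics.

## The problem

Post-glacial freshwater stickleback populations are a model system for
rapid, parallel evolution. Because their marine ancestors still exist,
studies measure freshwater evolution as the displacement of a lake
population from a *contemporary marine reference* in morphometric space —
implicitly assuming marine populations are phenotypically homogeneous, so
that it does not matter which marine site was sampled. `refdiv` is for
evolutionary ecologists who want to test that assumption, or to know how
sensitive their own divergence and parallelism estimates are to reference
choice.

## What it computes

Given specimen-level morphometrics (8 linear traits + lateral plate and
gill raker counts) from marine and freshwater sites:

1. **Allometric size correction** per trait and population,
   γᵢ = χᵢ − β(Lᵢ − L̄), with β the trait-on-length OLS slope and L̄ the
   dataset mean standard length, plus Brown–Forsythe variance screening.
2. **Morphospace PCA** (correlation matrix) with per-site centroids.
3. For every (marine reference *m*, freshwater site *f*) pair, the
   **divergence** |ΔPC1| and the **vector length** L = ‖c_f − c_m‖ over
   all axes; and for every pair of freshwater sites sharing a reference,
   the **trajectory angle** θ = arccos(v₁·v₂ / ‖v₁‖‖v₂‖) — small θ means
   parallel evolution, 90° is the null. A pooled "panmictic" marine
   reference is analysed alongside.
4. **Reference-effect tests**: divergence ~ reference + (1 | lake) mixed
   models (REML, between-within df, optional within-lake permutation
   calibration), and per-lake percent change 100(max − min)/max under
   reference substitution.
5. **Distance decay**: shortest *through-water* distances on a raster grid
   (8-connected Dijkstra), bioclim variable pruning at |r| > 0.80, climate
   PCA differences, and mixed-model regressions of divergence on
   geographic or environmental distance.

A hierarchical synthetic-data generator with known ground truth
(`sim_config()`, `generate_specimens()`) emulates the field design
(10 marine + 6 freshwater sites, 20–60 fish per site, realistic trait
variances, spatially autocorrelated site means) and backs the
parameter-recovery tests.

## Worked example

```r
library(refdiv)
res <- run_pipeline(run_config(seed = 1))
summary(res)
```

```
Morphospace PCA: PC1 38.7%, PC2 12.5%, PC3 10.1%
Per-reference mean PC1 divergence: 3.62-4.66
Percent change under reference substitution: 20%-27%
Theta: mean 39 deg (range 20-63); per-reference means 34-42
Reference effect on PC1 divergence: SS = 5.97, F(9, 45) = 478938621464823.81, p = <2e-16
Reference effect on vector length: SS = 4.55, F = 10.22
Divergence ~ distance: beta = 0.000849 (SE 0.00062), t = 1.38
Divergence ~ env PC2 difference: beta = -0.0693 (SE 0.055), t = -1.27
```

Reading this: PC1 carries the marine-freshwater contrast (39% of trait
variance). Mean divergence of a lake from a marine reference ranges from
3.6 to 4.7 PC1 units *depending only on which reference was used*, moving
any single lake's estimate by 20-27%; the reference effect is formally
significant both for single-axis divergence and for multivariate vector
length (F = 10.2). Mean trajectory angles of 34-42° (well below the 90°
null) indicate parallel freshwater evolution, but the strength of inferred
parallelism also shifts with the reference. The absurdly large PC1-F is a
documented degeneracy — when all freshwater centroids exceed all marine
centroids on PC1, |ΔPC1| is exactly additive and the residual is zero; use
the vector-length F. Per-reference detail sits in the result object, e.g.

```r
head(res$vectors$theta_summary, 3)
#>                    marine n_pairs mean_theta min_theta max_theta
#> 1            Kanaka Creek      15   38.82045  23.26911  56.79426
#> 2 Courtenay River Estuary      15   39.84524  23.73426  60.13792
#> 3           Canton Lagoon      15   40.30732  25.75979  61.76081
```

`run_pipeline(run_config(out_dir = "out"))` additionally writes every
table (corrected specimens, loadings, centroids, divergence, theta,
distances, model summaries) as CSV with a JSON run manifest, and
`plot(res)` draws the centroid morphospace with divergence vectors and the
per-reference divergence boxplots. A thin command-line front end with
`simulate` / `preprocess` / `analyze` / `full` subcommands is installed at
`inst/cli/refdiv`.

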