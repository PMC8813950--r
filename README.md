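# forestcloud

Do forests make clouds, or suppress them? `forestcloud` implements a
space-for-time observational pipeline for estimating the local effect of
forest cover on cloud-cover fraction from gridded rasters, for
land-surface and ecosystem–atmosphere researchers who want the full
estimator — windowed paired comparison, confounder control, attribution,
cloud-type decomposition, hotspot trends, scale dependency, and the
sensible-heat linkage — runnable and testable end to end on synthetic
scenes with known ground truth.

## The estimator

The **potential effect** of forests on clouds is the paired difference

```
ΔCloud = Cloud_forest − Cloud_nonforest
```

computed inside 9 × 9-pixel moving windows (0.45° at the native 0.05°
resolution) whose centres sit on a 5-pixel lattice, retained only where
the window contains recent forest change. Unchanged forest means baseline
tree cover > 0.5 with accumulated change < 0.05; unchanged non-forest is
the complement with water, snow/ice and wetland excluded, water pixels
and their one-pixel buffer masked. Windows over rough terrain (elevation
s.d. > 100 m) are rejected, since orographic lifting confounds the
contrast. The **actual effect** of deforestation replaces the pair:

```
ΔCloud_loss = Cloud_loss − Cloud_forest
```

for pixels whose accumulated net tree loss exceeds 0.15. Remaining
orographic leakage is removed by the per-window regression

```
Cloud = S_tree · tree + S_ele · elevation + c
```

whose sensitivities, multiplied by the window's tree-cover and elevation
differences, decompose ΔCloud into `ΔCloud_tree + ΔCloud_ele` and drive a
five-class attribution (Tree±, Orography±, other). Per ISCCP type
(cloud-top pressure × optical depth bins), the same estimator splits
ΔCloud across the nine cloud types with an exact sum identity, and the
dominant type per cell tells whether the effect is convection-led. Annual
ΔCloud_loss series over loss hotspots get OLS trends with
`total change = slope × inclusive years`; a rescaling experiment re-runs
everything at 0.1°–1° to show the mesoscale inhibition signal washing out
with aggregation; and window effects are matched against forest/non-forest
sensible-heat differences (ΔH) via a conversion-table lookup,
geometric-mean regression, and Spearman rank correlation.

## Worked example

```r
library(forestcloud)

scene <- generateScene(sceneConfig(seed = 1L, withTypes = TRUE))
cm    <- classifyScene(scene)
buf   <- bufferWaterMask(scene@waterMask)
cloud <- stackMean(scene@cloudYearly)

pot <- potentialEffects(cm, cloud, scene@elevation, buf)
act <- actualEffects(cm, cloud, scene@elevation, buf)
signFractions(aggregateToDisplay(pot, 0.5))
#> positive negative
#>      100        0
round(c(potential = mean(pot$delta), actual = mean(act$delta)), 4)
#> potential    actual
#>    0.0277   -0.0139
```

The scene was generated with a true tree sensitivity of +0.1 and the mean
tree-cover contrast between window classes is ≈ 0.27, so the potential
effect ≈ +0.028 says forests carry about 2.8 percentage points more cloud
than nearby open land — and every display cell shows enhancement. The
actual effect is negative: where forest was lost, cloud decreased, the
mirror image of the potential effect, which is exactly the consistency
the estimator is built to expose. Attribution recovers the truth:

```r
att <- attributeEffects(cm, cloud, treeMeanField(scene), scene@elevation, buf)
round(mean(att$windows$sTree), 3)
#> [1] 0.099
att$classShares
#> TREE_PLUS TREE_MINUS  ORO_PLUS ORO_MINUS     OTHER
#>       100          0         0         0         0
```

A shell entry point over the same stages lives in
`inst/scripts/forestcloud.R`
(`simulate … classify … effects … attribute … cloudtypes … trends …
heatlink … report`, YAML-configured, deterministic under `--seed`).

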