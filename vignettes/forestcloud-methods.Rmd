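---
title: "Estimating forest effects on cloud cover: model, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating forest effects on cloud cover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestcloud)
```

## The space-for-time estimator

Clouds respond to the land surface beneath them, but a naive comparison of
cloudiness over forest versus farmland mostly measures weather and
climate, not forests. The estimator in this package controls for shared
meteorology by differencing *coexisting adjacent* land states: inside a
small moving window, unchanged forest pixels and unchanged non-forest
pixels see the same synoptic conditions, so their multiyear mean
cloud-fraction difference

$$\Delta\mathrm{Cloud} = \mathrm{Cloud}_{forest} - \mathrm{Cloud}_{nonforest}$$

isolates the land-surface contribution. Positive values mean cloud
enhancement over forest, negative values inhibition (the signature of a
thermally driven mesoscale circulation whose subsiding branch sits over
the cooler, wetter forest). The *actual* effect of deforestation swaps
the pair — forest-loss pixels against nearby unchanged forest — and its
sign is expected to mirror the potential effect, since losing forest
moves the surface toward the non-forest state.

The key identification assumptions are (i) shared meteorology within a
window (window extent ≪ synoptic scales), (ii) stable pixel classes over
the averaging period (hence the "unchanged" thresholds), and (iii) no
residual confounder that co-varies with forest cover inside windows.
Terrain is the dominant such confounder — forests sit preferentially on
higher, rougher ground that itself lifts moist air — and is handled
twice: windows whose elevation standard deviation exceeds 100 m are
rejected outright, and the surviving effect is decomposed through the
per-window ordinary-least-squares model

$$\mathrm{Cloud} = S_{tree}\cdot \mathrm{tree} + S_{ele}\cdot \mathrm{elevation} + c$$

into tree-cover and orography contributions
($\Delta\mathrm{Cloud}_{tree} = S_{tree}\Delta\mathrm{Tree}$,
$\Delta\mathrm{Cloud}_{ele} = S_{ele}\Delta\mathrm{Ele}$). Sensitivities
and differences are averaged onto the 0.5° display grid *before* the
multiplication, so the decomposition is a cell-level statement; on a
scene where the true sensitivity is constant within a cell, averaging
commutes with the products and the decomposition is exact.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| window size | 9 | pixels (0.45° at 0.05°) | small enough for shared meteorology, large enough to hold both classes |
| window step | 5 | pixels | half-overlapping lattice; denser sampling without redundant windows |
| forest threshold | 0.5 | tree-cover fraction | forest/non-forest split on baseline cover; exactly 0.5 counts as non-forest (strict >) |
| change threshold | 0.05 | fraction | "unchanged" pixels and the window-retention trigger |
| net-loss threshold | 0.15 | fraction | forest-loss pixels; a stronger signal improves detectability against cloud noise |
| elevation s.d. max | 100 | m | rejects complex terrain where orographic clouds dominate |
| min class counts | 3 + 3 | pixels | not externally prescribed; chosen for mean stability and exposed in `windowSpec()` |
| display resolution | 0.5 | degrees | pooling scale for maps, sign shares and attribution |
| ISCCP boundaries | 440/680 hPa, 3.6/23 | — | the standard cloud-type diagram; boundary values fall to the higher-altitude / thinner bin |
| daytime hours | 8–16 inclusive | local hours | nine hourly values; endpoint semantics chosen inclusive |
| ΔH outlier cut | 200 | W/m² | excludes implausible conversion-table differences from the site-pair regression |

Gross turnover (accumulated loss + gain) is the default "change" measure
for the unchanged test, while the signed quantity (gain − loss) defines
net forest loss: a pixel with loss = gain = 0.2 is genuinely disturbed
and should not anchor an "unchanged" class. The alternative reading
(|gain − loss| for both) is available via
`classifierConfig(unchangedMetric = "signed")`, and the same switch
governs the window trigger.

## What the synthetic scenes emulate — and what they do not

`generateScene()` draws every input the pipeline consumes from a known
generative model: spatially correlated elevation (Gaussian random field,
e-folding length 8 cells, s.d. 50 m around 300 m) and baseline tree
cover (correlation length 6 cells, clipped to [0, 1] around 0.5); water
in the lowest-elevation cells plus a wetland sprinkle; contiguous
forest-loss blobs grown breadth-first from random forest seeds, each
losing a fixed fraction per year from a random start year; and cloud
stacks following

$$\mathrm{cloud}_y = \mathrm{clip}\big(b_0 + S_{tree}\,\mathrm{tree}_y +
  S_{ele}\,\mathrm{elevation} + \varepsilon_y(\mathbf{x}) + \eta_y,\ 0,\ 1\big)$$

with `tree_y` the baseline minus accumulated loss, a spatially
correlated noise field redrawn each year (weather), and a scene-wide
scalar per year (large-scale interannual variability). Regionally
varying sensitivity — including opposite signs, the observational
hallmark of enhancement versus mesoscale inhibition — comes as uniform,
west/east halves, or scattered sub-window patches. Monthly and hourly
stacks modulate the tree coupling with a seasonal cosine (peak month 7)
and a local-time Gaussian (peak hour 14); months from November through
March poleward of 50° are snow-flagged to nodata, mirroring the
snow-contamination masking of real cloud records. Cloud-type fields give
convection a share of the cloud that rises with tree cover and along
tree-cover gradients, led by stratocumulus, so convective types
preferentially carry the forest signal; the synthetic sensible-heat
conversion table sets ΔH proportional (+ noise) to the regional tree
sensitivity, encoding the sensible-heat mechanism that differentiates
the sign of the effect.

The generator does **not** simulate radiative transfer, diurnal
convection physics, orographic flow, wind-direction asymmetries, or any
actual circulation: inhibition regimes are encoded directly as negative
sensitivity rather than emerging from a circulation model. Passing tests
therefore demonstrate that the *estimator* recovers known structure
under the stated statistical assumptions — not that those assumptions
hold for any particular satellite record.

## Numerical choices

- **Ties and zeros.** Majority aggregation and modal land-cover pairs
  break ties to the smallest category code; zero deltas count as
  enhancement in sign splits (configurable); exact magnitude ties in the
  attribution break toward tree cover; dominant-cloud-type ties break to
  the smallest code; a zero total effect attributes to "other".
- **Nodata.** Aggregation means ignore nodata and only propagate it when
  a whole block is missing; class means require a configurable minimum
  of valid pixels; display cells with no samples are nodata; rejections
  (counts, terrain, rank deficiency) are typed outcomes that are tallied,
  never exceptions.
- **Regression.** Per-window sensitivities need ≥ 4 valid pixels (one
  more than parameters), a nonzero tree cover, and a full-rank design;
  constant elevation is rejected with a reason code. Trend p-values are
  two-tailed t-tests on the OLS slope; Spearman p uses the
  t-approximation.
- **Geometry.** Cell coordinates are centers, extents half-open, display
  binning floors coordinates to multiples of the display resolution, and
  window indexing follows R's 1-based convention.
- **Total change.** `total = slope × inclusive year count` (17 for
  2002–2018); this convention reproduces all four published
  trend→total pairs the package checks in its tests.
- **Eq. for ΔTree.** The annual tree-cover difference subtracts the
  accumulated loss-difference term, so accumulating loss over loss
  pixels drives ΔTree downward, consistent with its role as the driver
  of a strengthening actual effect; an additive reading would make ΔTree
  rise with loss, contradicting its own trajectory plots.
- **"Explained".** The reconstruction quality of
  $\Delta\mathrm{Cloud}_{tree}+\Delta\mathrm{Cloud}_{ele}$ is the squared
  Pearson correlation with the original (an $R^2$); a magnitude-ratio
  alternative is available via `method = "abs_ratio"`.

## Test design for stochastic properties

Two calibration choices deserve a note. The null-calibration check (a
scene with all sensitivities zero must produce a centred mean effect and
a ~50/50 sign split) uses *non-overlapping* windows (step = size): with
the default half-overlapping lattice adjacent windows share 44% of their
pixels, deltas are strongly cross-correlated, and the naive standard
error is too small for a ±2 SE assertion. The trend-recovery check pools
three replicate scenes and tests the mean recovered slope against the
empirical standard error of the replicates, again because a single
series' within-fit standard error understates the scene-to-scene
variability.

Problem sizes: unit and oracle tests run on 20×20 hand-built surfaces
and 64×64 five-year scenes; stochastic properties use 96–200 cell scenes
with the full 2002–2018 record; the null calibration uses a 320×320
scene (≈ 360 non-overlapping windows) and the scale experiment a
240×240 scene (12°, so 1° cells still leave loss-free "unchanged"
blocks). These sizes give each stochastic assertion a comfortable
effective sample while keeping the whole suite around a minute.

## Known limitations

- Geographic lat/lon only; no projections, no reprojection, no
  out-of-core tiling. I/O is plain-text ASCII grid; there is no GeoTIFF
  or NetCDF binding in this package.
- OLS sensitivities ignore spatial autocorrelation and nonlinearity; the
  attribution inherits those assumptions.
- The per-window estimator needs both classes present near forest
  change; heavily deforested landscapes at coarse aggregation can leave
  no "unchanged" pixels, which is itself the scale-dependency signal the
  rescaling experiment measures.
- One widely used description of the ISCCP legend inverts the altitude
  ordering of types 1–3 versus 7–9; this package follows the standard
  diagram (1–3 high, 7–9 low). The convective set {3, 7, 8} is unaffected.
- The sensible-heat linkage treats the conversion table as given (the
  combined H+G flux labelled "H" for simplicity); the package does not
  estimate surface energy balance from radiation components.
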