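Package: forestcloud
Title: Potential and Actual Effects of Forest Cover on Cloud Cover from Gridded Rasters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A space-for-time moving-window estimator of the local effect of
    forest cover on cloud-cover fraction from gridded rasters. Pairs unchanged
    forest with nearby unchanged non-forest pixels inside 9x9-pixel windows
    placed at locations of recent forest change, controls orographic
    confounding with a terrain-roughness filter and a per-window regression of
    cloud on tree cover and elevation, decomposes the effect into tree-cover
    and orography contributions, splits it across the nine ISCCP cloud types,
    tracks annual effects over forest-loss hotspots with linear trends, probes
    the scale dependency of the sign pattern across aggregation resolutions,
    and links window effects to forest/non-forest sensible-heat differences
    via a conversion-table lookup, geometric-mean regression and Spearman rank
    correlation. Ships a synthetic-scene generator with known ground truth so
    the full pipeline is testable without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'GridField-methods.R'
    'io.R'
    'synthetic.R'
    'classify.R'
    'windows.R'
    'attribution.R'
    'cloudtypes.R'
    'trends.R'
    'heatlink.R'
    'pipeline.R'
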