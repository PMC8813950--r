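#' @import methods
NULL

.AXIS_TOL <- 1e-9

.check_axis <- function(ax, res, what) {
  if (length(ax) < 1L) return(sprintf("%s axis is empty", what))
  if (length(ax) > 1L) {
    d <- diff(ax)
    if (any(d <= 0)) return(sprintf("%s axis not strictly increasing", what))
    if (any(abs(d - res) > .AXIS_TOL))
      return(sprintf("%s axis not evenly spaced at the declared resolution", what))
  }
  NULL
}

#' GridField: a georeferenced 2-D raster field
#'
#' The universal raster currency of the package: a numeric matrix with
#' cell-center latitude/longitude axes on a regular geographic grid.
#' Rows index latitude (south to north), columns longitude (west to east).
#' `NA` cells are nodata. Fields declared fraction-valued (cloud fraction,
#' tree-cover fraction, loss fraction) must lie in \[0, 1\] on valid cells.
#'
#' @slot values numeric matrix, `NA` = nodata.
#' @slot lat,lon numeric cell-center coordinates in degrees, strictly
#'   increasing and evenly spaced to within 1e-9 degree.
#' @slot resolution grid spacing in degrees per cell (> 0).
#' @slot variable,units name and units tag, e.g. `"cloud_fraction"` /
#'   `"1"`, `"elevation"` / `"m"`.
#' @slot fraction logical; `TRUE` declares the field fraction-valued.
#' @exportClass GridField
setClass("GridField",
  representation(values = "matrix", lat = "numeric", lon = "numeric",
                 resolution = "numeric", variable = "character",
                 units = "character", fraction = "logical"),
  prototype(variable = "field", units = "1", fraction = FALSE))

setValidity("GridField", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (length(object@resolution) != 1L || !is.finite(object@resolution) ||
      object@resolution <= 0) return("resolution must be a single positive number")
  if (nrow(v) != length(object@lat)) return("nrow(values) != length(lat)")
  if (ncol(v) != length(object@lon)) return("ncol(values) != length(lon)")
  for (msg in list(.check_axis(object@lat, object@resolution, "lat"),
                   .check_axis(object@lon, object@resolution, "lon")))
    if (!is.null(msg)) return(msg)
  if (isTRUE(object@fraction)) {
    ok <- v[!is.na(v)]
    if (length(ok) && (min(ok) < -1e-12 || max(ok) > 1 + 1e-12))
      return("fraction-valued field has values outside [0, 1]")
  }
  TRUE
})

#' GridStack: a time-indexed stack of GridFields sharing one geometry
#'
#' Slices are stored as a 3-D array `[lat, lon, time]`. Time labels are
#' numeric (calendar year, month of year 1-12, or UTC hour of day 0-23,
#' declared by `timeUnit`), unique and sorted.
#'
#' @slot values 3-D numeric array `[lat, lon, time]`, `NA` = nodata.
#' @slot time numeric labels, unique and strictly increasing.
#' @slot timeUnit one of `"year"`, `"month"`, `"hour"`.
#' @inheritSection GridField-class Slots
#' @exportClass GridStack
setClass("GridStack",
  representation(values = "array", lat = "numeric", lon = "numeric",
                 resolution = "numeric", variable = "character",
                 units = "character", fraction = "logical",
                 time = "numeric", timeUnit = "character"),
  prototype(variable = "field", units = "1", fraction = FALSE,
            timeUnit = "year"))

setValidity("GridStack", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("values must be a 3-D array [lat, lon, time]")
  if (dim(v)[1] != length(object@lat)) return("dim 1 != length(lat)")
  if (dim(v)[2] != length(object@lon)) return("dim 2 != length(lon)")
  if (dim(v)[3] != length(object@time)) return("dim 3 != length(time)")
  if (anyDuplicated(object@time)) return("time labels must be unique")
  if (is.unsorted(object@time, strictly = TRUE)) return("time labels must be sorted")
  if (!object@timeUnit %in% c("year", "month", "hour"))
    return("timeUnit must be year, month or hour")
  for (msg in list(.check_axis(object@lat, object@resolution, "lat"),
                   .check_axis(object@lon, object@resolution, "lon")))
    if (!is.null(msg)) return(msg)
  if (isTRUE(object@fraction)) {
    ok <- v[!is.na(v)]
    if (length(ok) && (min(ok) < -1e-12 || max(ok) > 1 + 1e-12))
      return("fraction-valued stack has values outside [0, 1]")
  }
  TRUE
})

#' Per-pixel land-state codes
#'
#' Integer codes of the [SurfaceClassMap-class] categories.
#' @export
CLASS_CODES <- c(UNCHANGED_FOREST = 1L, UNCHANGED_NONFOREST = 2L,
                 FOREST_LOSS = 3L, CHANGED_OTHER = 4L, MASKED = 5L)

#' IGBP-style land-cover codes used by the synthetic scenes
#'
#' A small subset of the IGBP legend sufficient for the pipeline: two forest
#' classes, two open vegetated classes, and the classes excluded from the
#' unchanged non-forest pool (water, snow/ice, wetland).
#' @export
LANDCOVER_CODES <- c(evergreen_broadleaf = 2L, deciduous_broadleaf = 4L,
                     grassland = 10L, wetland = 11L, cropland = 12L,
                     snow_ice = 15L, water = 17L)

#' SurfaceClassMap: per-pixel land state
#'
#' Exhaustive, mutually exclusive labels (see [CLASS_CODES]) with the
#' change diagnostics they were derived from: gross turnover
#' (accumulated loss + gain) and signed net change (gain - accumulated loss).
#'
#' @slot classes integer matrix of [CLASS_CODES].
#' @slot turnover,netChange numeric matrices (fractions).
#' @exportClass SurfaceClassMap
setClass("SurfaceClassMap",
  representation(classes = "matrix", turnover = "matrix", netChange = "matrix",
                 lat = "numeric", lon = "numeric", resolution = "numeric"))

setValidity("SurfaceClassMap", function(object) {
  cl <- object@classes
  if (!all(cl %in% CLASS_CODES)) return("class codes outside the declared set")
  if (!all(dim(cl) == dim(object@turnover)) ||
      !all(dim(cl) == dim(object@netChange))) return("companion field dims differ")
  if (nrow(cl) != length(object@lat) || ncol(cl) != length(object@lon))
    return("dims do not match axes")
  TRUE
})

#' SceneConfig: generative ground truth for a synthetic scene
#'
#' Parameters of the synthetic-scene generator. The cloud model is linear:
#' for year y, `cloud_y = clip(b0 + S_tree * tree_y + S_ele * elevation +
#' spatial noise + interannual noise_y, 0, 1)` where `tree_y` is baseline
#' tree cover minus accumulated loss. `S_tree` may vary regionally
#' (`sTreePattern`) with both signs, emulating cloud enhancement and
#' mesoscale-circulation inhibition regimes.
#'
#' @slot nLat,nLon scene size in cells.
#' @slot resolution degrees per cell.
#' @slot originLat,originLon south-west corner (edge) of the scene, degrees.
#' @slot years inclusive calendar years of the cloud record.
#' @slot seed integer RNG seed; a fixed seed reproduces the scene bit-exactly.
#' @slot b0 baseline cloud fraction.
#' @slot sTreeTrue,sTreeTrue2 cloud-fraction change per unit tree-cover
#'   fraction; `sTreeTrue2` is the second regime used by patterns other
#'   than `"uniform"`.
#' @slot sTreePattern `"uniform"`, `"halves"` (west/east split) or
#'   `"patches"` (sub-window blocks of the second regime).
#' @slot patchCount,patchSize count and side length (cells) of `"patches"`
#'   regime blocks.
#' @slot sEleTrue cloud-fraction change per metre of elevation.
#' @slot noiseSdSpatial,noiseSdInterannual cloud-fraction noise s.d.; the
#'   spatial field is drawn once per scene, the interannual term is an
#'   i.i.d. scene-wide scalar per year.
#' @slot correlationLength e-folding length (cells) of the spatial noise.
#' @slot eleMean,eleSd,eleCorrelationLength elevation model (m).
#' @slot treeSd,treeCorrelationLength baseline tree-cover model.
#' @slot lossPatchCount,lossPatchSize,lossRatePerYear forest-loss blobs:
#'   count, pixels per blob, and loss fraction removed per active year.
#' @slot waterFraction,wetlandFraction fractions of cells assigned water
#'   (lowest elevations) and wetland.
#' @slot snowLatMin months poleward of this latitude are snow-flagged.
#' @slot snowMonths months (1-12) snow-flagged in the band.
#' @slot seasonalPeakMonth,seasonalAmplitude month of maximum tree-cloud
#'   coupling and relative modulation depth in \[0,1\].
#' @slot diurnalPeakLocal local hour of maximum coupling for hourly stacks.
#' @slot effectGrowthPerYear additional cloud fraction per year added over
#'   loss pixels (injects a linear trend in the actual effect).
#' @slot deltaHperSTree W/m2 of forest-minus-non-forest sensible-heat
#'   difference per unit of `S_tree` (sets the conversion-table sign).
#' @slot deltaHNoiseSd W/m2 noise on conversion-table entries.
#' @slot withHourly,withTypes generate the optional hourly stack and the
#'   ISCCP per-type fields.
#' @exportClass SceneConfig
setClass("SceneConfig",
  representation(nLat = "integer", nLon = "integer", resolution = "numeric",
    originLat = "numeric", originLon = "numeric", years = "integer",
    seed = "integer", b0 = "numeric", sTreeTrue = "numeric",
    sTreeTrue2 = "numeric", sTreePattern = "character",
    patchCount = "integer", patchSize = "integer", sEleTrue = "numeric",
    noiseSdSpatial = "numeric", noiseSdInterannual = "numeric",
    correlationLength = "numeric", eleMean = "numeric", eleSd = "numeric",
    eleCorrelationLength = "numeric", treeSd = "numeric",
    treeCorrelationLength = "numeric", lossPatchCount = "integer",
    lossPatchSize = "integer", lossRatePerYear = "numeric",
    waterFraction = "numeric", wetlandFraction = "numeric",
    snowLatMin = "numeric", snowMonths = "integer",
    seasonalPeakMonth = "integer", seasonalAmplitude = "numeric",
    diurnalPeakLocal = "integer", effectGrowthPerYear = "numeric",
    deltaHperSTree = "numeric", deltaHNoiseSd = "numeric",
    withHourly = "logical", withTypes = "logical"))

setValidity("SceneConfig", function(object) {
  fr <- c(object@b0, object@waterFraction, object@wetlandFraction,
          object@lossRatePerYear, object@seasonalAmplitude)
  if (any(fr < 0) || any(fr > 1)) return("fraction parameters must lie in [0, 1]")
  if (object@noiseSdSpatial < 0 || object@noiseSdInterannual < 0)
    return("noise s.d. must be >= 0")
  if (!object@sTreePattern %in% c("uniform", "halves", "patches"))
    return("sTreePattern must be uniform, halves or patches")
  if (length(object@years) < 1L || is.unsorted(object@years, strictly = TRUE))
    return("years must be strictly increasing")
  if (object@nLat < 8L || object@nLon < 8L) return("scene must be at least 8x8")
  TRUE
})

#' SyntheticScene: a generated raster bundle with known ground truth
#'
#' Everything the pipeline consumes, generated from one [SceneConfig-class]:
#' elevation, baseline tree cover, yearly loss, gain, categorical land
#' cover, water mask, yearly/monthly (and optionally hourly) cloud stacks,
#' optional ISCCP per-type cloud fields, a synthetic sensible-heat
#' conversion table, plus the true regional tree sensitivity map and the
#' config used (for recovery tests).
#'
#' @exportClass SyntheticScene
setClass("SyntheticScene",
  representation(elevation = "GridField", tree2000 = "GridField",
    yearlyLoss = "GridStack", gain = "GridField", landcover = "GridField",
    waterMask = "GridField", cloudYearly = "GridStack",
    cloudMonthly = "GridStack", cloudHourly = "ANY", typeFractions = "list",
    ctp = "ANY", tau = "ANY",
    conversionTable = "data.frame", sTreeMap = "GridField",
    config = "SceneConfig"))

setValidity("SyntheticScene", function(object) {
  geom <- function(x) c(length(x@lat), length(x@lon))
  g0 <- geom(object@elevation)
  for (f in list(object@tree2000, object@gain, object@landcover,
                 object@waterMask, object@sTreeMap))
    if (!identical(geom(f), g0)) return("scene members disagree in geometry")
  if (!identical(geom(object@cloudYearly), g0) ||
      !identical(geom(object@yearlyLoss), g0))
    return("scene stacks disagree in geometry")
  lost <- apply(object@yearlyLoss@values, c(1, 2), sum)
  if (any(lost[object@tree2000@values <= 0] > 1e-12, na.rm = TRUE))
    return("loss present where baseline tree cover is zero")
  TRUE
})
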