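#' Hotspot and seasonality region presets
#'
#' Named bounding boxes (degrees, `lonMin/lonMax/latMin/latMax`). The
#' Southeast US, Europe, Amazon and Central Africa boxes are the
#' seasonality analysis boxes; the Indonesia and East Siberia boxes are
#' approximate outlines of the remaining forest-loss hotspots.
#'
#' @return named list of numeric length-4 vectors.
#' @export
regionPresets <- function() {
  list(southeast_us = c(lonMin = -97, lonMax = -75, latMin = 30, latMax = 40),
       europe = c(lonMin = 10, lonMax = 30, latMin = 47, latMax = 55),
       amazon = c(lonMin = -70, lonMax = -50, latMin = -16, latMax = -5),
       central_africa = c(lonMin = 10, lonMax = 33, latMin = -7.5, latMax = 0),
       indonesia = c(lonMin = 95, lonMax = 120, latMin = -5, latMax = 5),
       east_siberia = c(lonMin = 110, lonMax = 140, latMin = 50, latMax = 65))
}

#' Annual tree-cover difference between loss and unchanged-forest pixels
#'
#' The baseline difference plus the accumulated yearly loss differences:
#' `deltaTree_year = (Tree2000_loss - Tree2000_forest) -
#' sum_{2001}^{year} (Treeloss_loss - Treeloss_forest)`, so accumulating
#' loss over loss pixels drives the difference downward.
#'
#' @param classmap a [SurfaceClassMap-class].
#' @param tree2000 baseline tree-cover [GridField-class].
#' @param yearlyLoss per-year loss [GridStack-class] (years from 2001).
#' @param years years to report (subset of the study period).
#' @return data.frame with `year`, `deltaTree`.
#' @export
deltaTreeSeries <- function(classmap, tree2000, yearlyLoss,
                            years = timeAxis(yearlyLoss)) {
  isLoss <- classmap@classes == CLASS_CODES[["FOREST_LOSS"]]
  isForest <- classmap@classes == CLASS_CODES[["UNCHANGED_FOREST"]]
  if (!any(isLoss) || !any(isForest))
    stop("both FOREST_LOSS and UNCHANGED_FOREST pixels are required",
         call. = FALSE)
  base <- mean(tree2000@values[isLoss], na.rm = TRUE) -
    mean(tree2000@values[isForest], na.rm = TRUE)
  lossYears <- yearlyLoss@time
  perYearDiff <- vapply(seq_along(lossYears), function(k) {
    v <- yearlyLoss@values[, , k]
    mean(v[isLoss], na.rm = TRUE) - mean(v[isForest], na.rm = TRUE)
  }, 0)
  cumDiff <- cumsum(perYearDiff)
  dt <- vapply(years, function(y) {
    keep <- lossYears <= y
    base - if (any(keep)) cumDiff[max(which(keep))] else 0
  }, 0)
  data.frame(year = years, deltaTree = dt)
}

#' Annual series of the actual effect over a hotspot region
#'
#' Per year, the mean forest-loss minus unchanged-forest cloud difference
#' over display cells inside the region whose tree-cover loss fraction
#' exceeds `lossFractionMin` (default 0.05).
#'
#' @param cloudYearly yearly cloud [GridStack-class].
#' @param classmap a [SurfaceClassMap-class].
#' @param yearlyLoss per-year loss [GridStack-class] (for the cell loss
#'   fraction).
#' @param region numeric `c(lonMin, lonMax, latMin, latMax)` or a preset
#'   name from [regionPresets()]; `NULL` uses the whole grid.
#' @param lossFractionMin display-cell accumulated-loss threshold.
#' @param elevation,waterBuffer,spec as in [actualEffects()].
#' @param displayRes display grid resolution in degrees.
#' @return data.frame with `year`, `delta`, `n` (qualifying cells).
#' @export
annualEffectSeries <- function(cloudYearly, classmap, yearlyLoss,
                               region = NULL, lossFractionMin = 0.05,
                               elevation = NULL, waterBuffer = NULL,
                               spec = windowSpec(), displayRes = 0.5) {
  if (is.character(region)) region <- regionPresets()[[region]]
  windows <- placeWindows(classmap, spec)
  totalLoss <- apply(yearlyLoss@values, c(1, 2), sum)
  # display-cell loss fraction by half-open binning of fine pixels
  pixLat <- rep(classmap@lat, times = length(classmap@lon))
  pixLon <- rep(classmap@lon, each = length(classmap@lat))
  key <- paste(.coarse_bin(pixLat, displayRes), .coarse_bin(pixLon, displayRes))
  cellLoss <- tapply(as.vector(totalLoss), key, mean, na.rm = TRUE)

  years <- cloudYearly@time
  rows <- lapply(years, function(y) {
    sam <- actualEffects(classmap, getSlice(cloudYearly, y), elevation,
                         waterBuffer, spec, windows)
    if (!nrow(sam)) return(data.frame(year = y, delta = NA_real_, n = 0L))
    em <- aggregateToDisplay(sam, displayRes)
    d <- em@delta
    ok <- !is.na(d@values)
    cellLat <- matrix(d@lat, nrow(d@values), ncol(d@values))[ok]
    cellLon <- matrix(d@lon, nrow(d@values), ncol(d@values), byrow = TRUE)[ok]
    val <- d@values[ok]
    ckey <- paste(.coarse_bin(cellLat, displayRes), .coarse_bin(cellLon, displayRes))
    lf <- cellLoss[ckey]
    keep <- !is.na(lf) & lf > lossFractionMin
    if (!is.null(region))
      keep <- keep & cellLon >= region["lonMin"] & cellLon <= region["lonMax"] &
        cellLat >= region["latMin"] & cellLat <= region["latMax"]
    data.frame(year = y, delta = if (any(keep)) mean(val[keep]) else NA_real_,
               n = sum(keep))
  })
  out <- do.call(rbind, rows)
  if (all(out$n == 0L))
    stop("no display cells qualify (region empty or loss fraction too low)",
         call. = FALSE)
  out
}

#' Linear trend of an annual effect series
#'
#' OLS of the effect (converted to percent cloud fraction) on calendar
#' year; two-tailed t-test p on the slope; the total change over the
#' period is `slope * inclusive year count` (17 for 2002-2018).
#'
#' @param series data.frame with `year` and `delta` (cloud fraction)
#'   columns, at least 3 years.
#' @return list of class `TrendResult`: `slope` (%/year), `intercept`,
#'   `pValue`, `totalChange` (% over the period), `nYears`.
#' @export
fitTrend <- function(series) {
  ok <- !is.na(series$delta)
  year <- series$year[ok]
  pct <- series$delta[ok] * 100
  stopifnot(length(year) >= 3L)
  fit <- stats::lm(pct ~ year)
  slope <- unname(stats::coef(fit)[2])
  p <- if (length(unique(pct)) < 2L) NA_real_ else
    summary(fit)$coefficients[2, 4]
  nYears <- max(year) - min(year) + 1L
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 pValue = p, totalChange = slope * nYears, nYears = nYears),
            class = "TrendResult")
}

#' @export
print.TrendResult <- function(x, ...) {
  cat(sprintf("trend %+0.4f %%/year over %d years; total %+0.2f%%; p = %s\n",
              x$slope, x$nYears, x$totalChange,
              if (is.na(x$pValue)) "NA" else format.pval(x$pValue, digits = 2)))
  invisible(x)
}

#' Default window parameter combinations per resolution
#'
#' Two window-size/step combinations for each target resolution of the
#' scale experiment, shrinking the pixel window as cells coarsen so the
#' physical search extent stays comparable.
#'
#' @return data.frame with `resolution`, `windowSize`, `step`, `displayRes`.
#' @export
scaleConfigs <- function() {
  data.frame(
    resolution = c(0.05, 0.05, 0.1, 0.1, 0.25, 0.25, 0.5, 0.5, 1, 1),
    windowSize = c(9L, 11L, 5L, 9L, 3L, 5L, 3L, 5L, 3L, 3L),
    step       = c(5L, 5L, 3L, 5L, 1L, 2L, 1L, 2L, 1L, 2L),
    displayRes = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 1, 1, 2, 2))
}

#' Scale dependency of the potential effect
#'
#' Re-runs the whole chain at coarser resolutions: cloud and fraction
#' fields are block-mean aggregated, land cover by majority, the water
#' mask by majority vote; the surface is re-classified, the window
#' estimator re-run with per-resolution window parameters, and the
#' enhancement/inhibition shares reported. Mesoscale inhibition patches
#' smaller than the aggregated cell wash out, so the inhibition share
#' shrinks with coarsening.
#'
#' @param scene a [SyntheticScene-class] whose grid the coarsest factor
#'   divides.
#' @param configs data.frame as [scaleConfigs()].
#' @param classifier a [classifierConfig()].
#' @return data.frame: one row per (resolution, parameter combination)
#'   with `positive`, `negative` shares (percent) and sample counts.
#' @export
rescaleExperiment <- function(scene, configs = scaleConfigs(),
                              classifier = classifierConfig()) {
  baseRes <- scene@tree2000@resolution
  cloudMean <- stackMean(scene@cloudYearly)
  rows <- lapply(seq_len(nrow(configs)), function(i) {
    res <- configs$resolution[i]
    f <- as.integer(round(res / baseRes))
    if (abs(res / baseRes - f) > 1e-9)
      stop("target resolution is not an integer multiple of the scene resolution",
           call. = FALSE)
    agg <- function(x) if (f == 1L) x else aggregateMean(x, f)
    aggMaj <- function(x) if (f == 1L) x else aggregateMajor(x, f)
    tree <- agg(scene@tree2000)
    loss <- agg(scene@yearlyLoss)
    gain <- agg(scene@gain)
    lc <- aggMaj(scene@landcover)
    elev <- agg(scene@elevation)
    water <- aggMaj(scene@waterMask)
    cloud <- agg(cloudMean)
    ch <- computeChange(tree, loss, gain)
    cm <- classifyPixels(tree, ch$turnover, ch$netChange, lc, classifier)
    spec <- windowSpec(size = configs$windowSize[i], step = configs$step[i])
    sam <- potentialEffects(cm, cloud, elev, bufferWaterMask(water), spec)
    if (nrow(sam) == 0)
      return(data.frame(resolution = res, windowSize = spec$size,
                        step = spec$step, positive = NA_real_,
                        negative = NA_real_, nSamples = 0L, nCells = 0L))
    em <- aggregateToDisplay(sam, configs$displayRes[i])
    sf <- signFractions(em)
    data.frame(resolution = res, windowSize = spec$size, step = spec$step,
               positive = sf[["positive"]], negative = sf[["negative"]],
               nSamples = nrow(sam), nCells = sum(!is.na(em@delta@values)))
  })
  do.call(rbind, rows)
}
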