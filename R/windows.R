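#' Moving-window specification
#'
#' Geometry and filters of the space-for-time window estimator: odd window
#' side (default 9 pixels = 0.45 degrees at 0.05), centre spacing (default
#' 5 pixels, half-overlapping windows), minimum per-class pixel counts
#' (default 3, for mean stability), the terrain-roughness filter (reject
#' windows whose elevation s.d. exceeds 100 m) and the change trigger (a
#' window is retained only if it contains at least one pixel whose forest
#' change exceeds 0.05).
#'
#' @param size odd integer >= 3.
#' @param step integer in `[1, size]`.
#' @param minForest,minNonforest,minLoss minimum valid pixels per class.
#' @param elevSdMax metres.
#' @param triggerThreshold change fraction for window retention.
#' @return a list of class `WindowSpec`.
#' @export
windowSpec <- function(size = 9L, step = 5L, minForest = 3L,
                       minNonforest = 3L, minLoss = 3L, elevSdMax = 100,
                       triggerThreshold = 0.05) {
  size <- as.integer(size); step <- as.integer(step)
  stopifnot(size >= 3L, size %% 2L == 1L, step >= 1L, step <= size,
            minForest >= 1L, minNonforest >= 1L, minLoss >= 1L)
  structure(list(size = size, step = step, minForest = as.integer(minForest),
                 minNonforest = as.integer(minNonforest),
                 minLoss = as.integer(minLoss), elevSdMax = elevSdMax,
                 triggerThreshold = triggerThreshold), class = "WindowSpec")
}

#' Place moving windows on a classified grid
#'
#' Windows are fully interior (no partial edge windows), their centres on
#' a lattice with spacing `spec$step`; a window is retained only when it
#' contains at least one pixel whose forest-change measure exceeds the
#' trigger threshold, anchoring every comparison near actual forest change.
#'
#' @param classmap a [SurfaceClassMap-class].
#' @param spec a [windowSpec()].
#' @param changeField optional matrix of the change measure; defaults to
#'   the classmap's gross turnover.
#' @return data.frame with one row per retained window: `row0`, `col0`
#'   (top-left 1-based indices), `centerRow`, `centerCol`, `lat`, `lon`.
#'   A grid smaller than the window yields an empty frame with a warning.
#' @export
placeWindows <- function(classmap, spec = windowSpec(), changeField = NULL) {
  n <- nrow(classmap@classes); p <- ncol(classmap@classes)
  sz <- spec$size
  empty <- data.frame(row0 = integer(), col0 = integer(),
                      centerRow = integer(), centerCol = integer(),
                      lat = numeric(), lon = numeric())
  if (n < sz || p < sz) {
    warning("grid smaller than the window size; no windows placed")
    return(empty)
  }
  if (is.null(changeField)) changeField <- classmap@turnover
  trig <- !is.na(changeField) & changeField > spec$triggerThreshold
  r0 <- seq(1L, n - sz + 1L, by = spec$step)
  c0 <- seq(1L, p - sz + 1L, by = spec$step)
  grid <- expand.grid(row0 = r0, col0 = c0)
  keep <- vapply(seq_len(nrow(grid)), function(k) {
    any(trig[grid$row0[k]:(grid$row0[k] + sz - 1L),
             grid$col0[k]:(grid$col0[k] + sz - 1L)])
  }, logical(1))
  grid <- grid[keep, , drop = FALSE]
  half <- (sz - 1L) %/% 2L
  grid$centerRow <- grid$row0 + half
  grid$centerCol <- grid$col0 + half
  grid$lat <- classmap@lat[grid$centerRow]
  grid$lon <- classmap@lon[grid$centerCol]
  rownames(grid) <- NULL
  grid
}

#' Terrain-roughness filter for one window
#'
#' Fails when the standard deviation of elevation over unmasked window
#' pixels exceeds `spec$elevSdMax` (complex terrain, where the
#' forest/non-forest contrast would be confounded by orographic clouds)
#' or when no valid elevation is available.
#'
#' @param elevWindow numeric matrix/vector of window elevations (m).
#' @param spec a [windowSpec()].
#' @return logical pass/fail with the computed s.d. as attribute `"sd"`.
#' @export
elevationFilter <- function(elevWindow, spec = windowSpec()) {
  v <- elevWindow[!is.na(elevWindow)]
  if (length(v) < 2L) return(structure(FALSE, sd = NA_real_))
  s <- stats::sd(v)
  structure(s <= spec$elevSdMax, sd = s)
}

# per-window paired class means; returns a row list or a rejection reason
.window_sample <- function(rows, cols, classes, fieldV, elevV, bufferV,
                           classA, classB, minA, minB, elevSdMax) {
  cl <- classes[rows, cols]
  if (!is.null(bufferV)) cl[bufferV[rows, cols]] <- CLASS_CODES[["MASKED"]]
  elevSd <- NA_real_
  if (!is.null(elevV)) {
    ev <- elevV[rows, cols]
    ev <- ev[!is.na(ev) & cl != CLASS_CODES[["MASKED"]]]
    if (length(ev) < 2L) return(list(reason = "elevation_sd"))
    elevSd <- stats::sd(ev)
    if (elevSd > elevSdMax) return(list(reason = "elevation_sd"))
  }
  fv <- fieldV[rows, cols]
  a <- fv[cl == classA & !is.na(fv)]
  b <- fv[cl == classB & !is.na(fv)]
  if (length(a) < minA) return(list(reason = "min_count_a"))
  if (length(b) < minB) return(list(reason = "min_count_b"))
  list(meanA = mean(a), meanB = mean(b), nA = length(a), nB = length(b),
       elevSd = elevSd)
}

#' Paired class-mean differences over moving windows
#'
#' The core estimator: for every retained window, the mean of `field` over
#' pixels of `classA` minus the mean over pixels of `classB`, subject to
#' the water buffer, the elevation filter and the minimum-count rules.
#' Rejections are typed outcomes, tallied in the `"counts"` attribute
#' (`placed = retained + rejected`).
#'
#' @param classmap a [SurfaceClassMap-class].
#' @param field a [GridField-class] (e.g. a multiyear mean cloud fraction,
#'   LST, ET, soil moisture, tree cover or elevation).
#' @param classA,classB codes from [CLASS_CODES].
#' @param minA,minB minimum valid pixels per class.
#' @param elevation optional [GridField-class] for the roughness filter.
#' @param waterBuffer optional logical matrix from [bufferWaterMask()].
#' @param spec a [windowSpec()].
#' @param windows optional pre-placed window frame from [placeWindows()].
#' @return data.frame with columns `lat`, `lon`, `meanA`, `meanB`,
#'   `delta` (= meanA - meanB), `nA`, `nB`, `elevSd`.
#' @export
classDeltaSamples <- function(classmap, field, classA, classB,
                              minA = 3L, minB = 3L, elevation = NULL,
                              waterBuffer = NULL, spec = windowSpec(),
                              windows = NULL) {
  if (is.null(windows)) windows <- placeWindows(classmap, spec)
  fieldV <- field@values
  elevV <- if (is.null(elevation)) NULL else elevation@values
  sz <- spec$size
  out <- vector("list", nrow(windows))
  counts <- c(placed = nrow(windows), retained = 0L, elevation_sd = 0L,
              min_count_a = 0L, min_count_b = 0L)
  for (k in seq_len(nrow(windows))) {
    rows <- windows$row0[k]:(windows$row0[k] + sz - 1L)
    cols <- windows$col0[k]:(windows$col0[k] + sz - 1L)
    s <- .window_sample(rows, cols, classmap@classes, fieldV, elevV,
                        bufferV = waterBuffer, classA = classA,
                        classB = classB, minA = minA, minB = minB,
                        elevSdMax = spec$elevSdMax)
    if (!is.null(s$reason)) {
      counts[s$reason] <- counts[s$reason] + 1L
    } else {
      counts["retained"] <- counts["retained"] + 1L
      out[[k]] <- data.frame(lat = windows$lat[k], lon = windows$lon[k],
                             meanA = s$meanA, meanB = s$meanB,
                             delta = s$meanA - s$meanB, nA = s$nA,
                             nB = s$nB, elevSd = s$elevSd)
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) res <- data.frame(lat = numeric(), lon = numeric(),
                                      meanA = numeric(), meanB = numeric(),
                                      delta = numeric(), nA = integer(),
                                      nB = integer(), elevSd = numeric())
  rownames(res) <- NULL
  attr(res, "counts") <- counts
  res
}

#' Potential effect of forests on cloud cover
#'
#' Per retained window, the unchanged-forest minus unchanged-non-forest
#' mean of `field` (positive = enhancement over forest, negative =
#' inhibition). Columns follow the forest/non-forest naming.
#'
#' @inheritParams classDeltaSamples
#' @return data.frame with `lat`, `lon`, `meanForest`, `meanNonforest`,
#'   `delta`, `nForest`, `nNonforest`, `elevSd` and a `"counts"` attribute.
#' @export
potentialEffects <- function(classmap, field, elevation = NULL,
                             waterBuffer = NULL, spec = windowSpec(),
                             windows = NULL) {
  res <- classDeltaSamples(classmap, field,
                           CLASS_CODES[["UNCHANGED_FOREST"]],
                           CLASS_CODES[["UNCHANGED_NONFOREST"]],
                           spec$minForest, spec$minNonforest, elevation,
                           waterBuffer, spec, windows)
  names(res)[names(res) == "meanA"] <- "meanForest"
  names(res)[names(res) == "meanB"] <- "meanNonforest"
  names(res)[names(res) == "nA"] <- "nForest"
  names(res)[names(res) == "nB"] <- "nNonforest"
  res
}

#' Actual effect of forest loss on cloud cover
#'
#' Per retained window, the forest-loss minus unchanged-forest mean of
#' `field`: the realized cloud impact at locations that lost forest.
#'
#' @inheritParams classDeltaSamples
#' @return data.frame with `lat`, `lon`, `meanLoss`, `meanForest`,
#'   `delta`, `nLoss`, `nForest`, `elevSd` and a `"counts"` attribute.
#' @export
actualEffects <- function(classmap, field, elevation = NULL,
                          waterBuffer = NULL, spec = windowSpec(),
                          windows = NULL) {
  res <- classDeltaSamples(classmap, field, CLASS_CODES[["FOREST_LOSS"]],
                           CLASS_CODES[["UNCHANGED_FOREST"]],
                           spec$minLoss, spec$minForest, elevation,
                           waterBuffer, spec, windows)
  names(res)[names(res) == "meanA"] <- "meanLoss"
  names(res)[names(res) == "meanB"] <- "meanForest"
  names(res)[names(res) == "nA"] <- "nLoss"
  names(res)[names(res) == "nB"] <- "nForest"
  res
}

#' EffectMap: window samples binned to a display grid
#'
#' @slot delta [GridField-class] of per-cell unweighted mean deltas
#'   (nodata where no samples fall).
#' @slot count [GridField-class] of per-cell sample counts.
#' @exportClass EffectMap
setClass("EffectMap", representation(delta = "GridField", count = "GridField"))

setMethod("show", "EffectMap", function(object) {
  cat("EffectMap:\n  ")
  show(object@delta)
  cat(sprintf("  %d samples in %d cells\n", sum(object@count@values, na.rm = TRUE),
              sum(!is.na(object@delta@values))))
})

#' Aggregate window samples to a display grid
#'
#' Samples are binned half-open by their window-centre coordinates into
#' cells of `displayRes` degrees aligned to multiples of the resolution;
#' each display cell holds the unweighted mean of its sample deltas.
#'
#' @param samples data.frame with `lat`, `lon`, `delta` columns.
#' @param displayRes display cell size in degrees (default 0.5).
#' @param deltaColumn column to aggregate (default `"delta"`).
#' @return an [EffectMap-class].
#' @export
aggregateToDisplay <- function(samples, displayRes = 0.5,
                               deltaColumn = "delta") {
  stopifnot(nrow(samples) > 0)
  bLat <- .coarse_bin(samples$lat, displayRes)
  bLon <- .coarse_bin(samples$lon, displayRes)
  rLat <- range(bLat); rLon <- range(bLon)
  nr <- rLat[2] - rLat[1] + 1L; ncl <- rLon[2] - rLon[1] + 1L
  dm <- matrix(NA_real_, nr, ncl)
  cm <- matrix(0, nr, ncl)
  ii <- bLat - rLat[1] + 1L; jj <- bLon - rLon[1] + 1L
  key <- paste(ii, jj)
  agg <- tapply(samples[[deltaColumn]], key, mean)
  cnt <- tapply(samples[[deltaColumn]], key, length)
  pos <- do.call(rbind, lapply(strsplit(names(agg), " "), as.integer))
  dm[pos] <- agg
  cm[pos] <- cnt
  lat <- (rLat[1] + seq_len(nr) - 0.5) * displayRes
  lon <- (rLon[1] + seq_len(ncl) - 0.5) * displayRes
  new("EffectMap",
      delta = gridField(dm, displayRes, lat = lat, lon = lon,
                        variable = "delta", units = "1"),
      count = gridField(cm, displayRes, lat = lat, lon = lon,
                        variable = "n_samples", units = "1"))
}

#' Enhancement / inhibition shares of an effect map
#'
#' Percent of valid display cells with positive (enhancement; zeros count
#' as enhancement) and negative (inhibition) deltas; the two sum to 100.
#'
#' @param effectMap an [EffectMap-class] or [GridField-class] of deltas.
#' @param zeroAsPositive count exact zeros as enhancement (default TRUE).
#' @return named numeric `c(positive = , negative = )` in percent.
#' @export
signFractions <- function(effectMap, zeroAsPositive = TRUE) {
  v <- if (is(effectMap, "EffectMap")) effectMap@delta@values else effectMap@values
  v <- v[!is.na(v)]
  if (!length(v)) return(c(positive = NA_real_, negative = NA_real_))
  pos <- if (zeroAsPositive) mean(v >= 0) else mean(v > 0)
  c(positive = 100 * pos, negative = 100 * (1 - pos))
}

#' Latitudinal profile of enhancement and inhibition
#'
#' Per latitude band of `bandWidth` degrees, the mean of positive deltas
#' and the mean of negative deltas with their cell counts; empty bands are
#' `NA`.
#'
#' @param effectMap an [EffectMap-class].
#' @param bandWidth band width in degrees.
#' @return data.frame with `bandSouth`, `bandCenter`, `meanEnhancement`,
#'   `nEnhancement`, `meanInhibition`, `nInhibition`.
#' @export
latitudinalProfile <- function(effectMap, bandWidth = 1) {
  d <- effectMap@delta
  v <- d@values
  latCell <- matrix(d@lat, nrow(v), ncol(v))
  ok <- !is.na(v)
  band <- floor(latCell[ok] / bandWidth)
  val <- v[ok]
  bands <- sort(unique(band))
  out <- do.call(rbind, lapply(bands, function(b) {
    x <- val[band == b]
    data.frame(bandSouth = b * bandWidth,
               bandCenter = (b + 0.5) * bandWidth,
               meanEnhancement = if (any(x >= 0)) mean(x[x >= 0]) else NA_real_,
               nEnhancement = sum(x >= 0),
               meanInhibition = if (any(x < 0)) mean(x[x < 0]) else NA_real_,
               nInhibition = sum(x < 0))
  }))
  rownames(out) <- NULL
  out
}

#' Month of the maximum seasonal effect
#'
#' The snow-free month maximizing |delta|; ties break to the earliest
#' month. Months outside `snowfreeMonths` or with missing values are
#' excluded.
#'
#' @param monthlyDelta numeric length-12 vector (possibly with `NA` gaps).
#' @param snowfreeMonths integer months 1-12 considered.
#' @return integer month, or `NA` if no candidate month exists.
#' @export
seasonalMaxMonth <- function(monthlyDelta, snowfreeMonths = 1:12) {
  stopifnot(length(monthlyDelta) == 12L)
  cand <- intersect(snowfreeMonths, which(!is.na(monthlyDelta)))
  if (!length(cand)) return(NA_integer_)
  cand[which.max(abs(monthlyDelta[cand]))]
}

#' Local hour of the maximum diurnal effect
#'
#' Shifts a 24-entry UTC series to local time by `round(lon / 15)` hours
#' and returns the local hour (0-23) with the largest |delta| (the largest
#' effect regardless of sign); ties break to the earliest local hour.
#'
#' @param hourlyDelta numeric length-24 vector indexed by UTC hour 0-23.
#' @param lon longitude in degrees.
#' @return integer local hour in 0-23.
#' @export
diurnalMaxHour <- function(hourlyDelta, lon) {
  stopifnot(length(hourlyDelta) == 24L)
  offset <- round(lon / 15)
  localHour <- (0:23 + offset) %% 24
  local <- numeric(24)
  local[localHour + 1] <- hourlyDelta
  ok <- which(!is.na(local))
  if (!length(ok)) return(NA_integer_)
  as.integer(ok[which.max(abs(local[ok]))] - 1L)
}
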