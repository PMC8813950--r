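#' Dominant land-cover pair of one window
#'
#' Modal land-cover class among the unchanged-forest pixels and among the
#' unchanged-non-forest pixels of a window (majority ties break to the
#' smallest code), giving the land-conversion key used against a
#' sensible-heat conversion table.
#'
#' @param classmap a [SurfaceClassMap-class].
#' @param landcover [GridField-class] of integer codes.
#' @param row0,col0 1-based top-left window indices.
#' @param spec a [windowSpec()].
#' @return list with `forestClass`, `nonforestClass`; or `list(reason =
#'   "empty_class")` when either class is absent.
#' @export
dominantPair <- function(classmap, landcover, row0, col0,
                         spec = windowSpec()) {
  rows <- row0:(row0 + spec$size - 1L)
  cols <- col0:(col0 + spec$size - 1L)
  cl <- classmap@classes[rows, cols]
  lc <- landcover@values[rows, cols]
  modal <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_integer_)
    as.integer(which.max(tabulate(as.integer(x))))
  }
  fc <- modal(lc[cl == CLASS_CODES[["UNCHANGED_FOREST"]]])
  nc <- modal(lc[cl == CLASS_CODES[["UNCHANGED_NONFOREST"]]])
  if (is.na(fc) || is.na(nc)) return(list(reason = "empty_class"))
  list(forestClass = fc, nonforestClass = nc)
}

#' Look up a sensible-heat difference for a land conversion
#'
#' Exact-key lookup of the forest-to-non-forest sensible-heat change at
#' the 1-degree cell enclosing the given coordinates. A missing key is a
#' typed missing value (`NA`), never zero.
#'
#' @param forestClass,nonforestClass land-cover codes.
#' @param lat,lon coordinates in degrees.
#' @param table data.frame with `cellLat`, `cellLon`, `forestClass`,
#'   `nonforestClass`, `deltaH` columns (W/m2).
#' @param cellRes conversion-table cell size in degrees.
#' @return `deltaH` in W/m2 or `NA`.
#' @export
lookupDeltaH <- function(forestClass, nonforestClass, lat, lon, table,
                         cellRes = 1) {
  cl <- floor(lat / cellRes) * cellRes + cellRes / 2
  cn <- floor(lon / cellRes) * cellRes + cellRes / 2
  hit <- which(abs(table$cellLat - cl) < 1e-9 &
               abs(table$cellLon - cn) < 1e-9 &
               table$forestClass == forestClass &
               table$nonforestClass == nonforestClass)
  if (!length(hit)) NA_real_ else table$deltaH[hit[1]]
}

#' Daytime mean of an hourly sensible-heat series
#'
#' Mean over local hours 8 through 16 inclusive (nine hourly values).
#'
#' @param hourly numeric length-24 vector indexed by local hour 0-23.
#' @return W/m2.
#' @export
daytimeMeanH <- function(hourly) {
  stopifnot(length(hourly) == 24L)
  mean(hourly[9:17])
}

#' Match site pairs to an effect map
#'
#' For each forest/non-forest site pair, reads the window effect at the
#' display cell containing the midpoint of the line linking the two
#' sites (intended for a 1-degree aggregation built without the
#' elevation-s.d. criterion or the water buffer). Pairs are excluded —
#' values untouched — when the matched effect is missing or when the
#' sensible-heat difference exceeds `outlierMax`.
#'
#' @param pairs data.frame with `latForest`, `lonForest`, `latNonforest`,
#'   `lonNonforest`, `deltaH` columns.
#' @param effectMap an [EffectMap-class].
#' @param outlierMax W/m2 exclusion threshold (default 200).
#' @return `pairs` with added `deltaCloud`, `excluded`, `reason`.
#' @export
matchSitePairs <- function(pairs, effectMap, outlierMax = 200) {
  d <- effectMap@delta
  res <- d@resolution
  southEdge <- d@lat[1] - res / 2
  westEdge <- d@lon[1] - res / 2
  midLat <- (pairs$latForest + pairs$latNonforest) / 2
  midLon <- (pairs$lonForest + pairs$lonNonforest) / 2
  i <- floor((midLat - southEdge) / res) + 1
  j <- floor((midLon - westEdge) / res) + 1
  inGrid <- i >= 1 & i <= nrow(d@values) & j >= 1 & j <= ncol(d@values)
  dc <- rep(NA_real_, nrow(pairs))
  dc[inGrid] <- d@values[cbind(i[inGrid], j[inGrid])]
  pairs$deltaCloud <- dc
  pairs$excluded <- FALSE
  pairs$reason <- NA_character_
  miss <- is.na(dc)
  pairs$excluded[miss] <- TRUE
  pairs$reason[miss] <- "missing deltaCloud"
  outl <- !miss & pairs$deltaH > outlierMax
  pairs$excluded[outl] <- TRUE
  pairs$reason[outl] <- "deltaH outlier"
  pairs
}

#' Geometric mean regression
#'
#' The symmetric line fit used when both variables carry error:
#' `slope = sign(r) * sd(y) / sd(x)`, intercept through the means.
#' Exchanging the axes inverts the slope exactly.
#'
#' @param x,y paired numeric vectors, n >= 3, both with nonzero variance.
#' @return list with `slope`, `intercept`, `r` (Pearson correlation).
#' @export
gmRegression <- function(x, y) {
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  stopifnot(length(x) >= 3L)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("zero variance in x or y", call. = FALSE)
  r <- stats::cor(x, y)
  slope <- sign(r) * sy / sx
  list(slope = slope, intercept = mean(y) - slope * mean(x), r = r)
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Pearson correlation of (average-tie) ranks; two-tailed p from
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors; n >= 4 for a finite p.
#' @return list with `rho`, `pValue`, `n`.
#' @export
rankCorrelation <- function(x, y) {
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopifnot(n >= 3L)
  rho <- stats::cor(rank(x), rank(y))
  p <- if (n < 4L || is.na(rho)) NA_real_
  else if (abs(rho) >= 1) 0
  else 2 * stats::pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), df = n - 2)
  list(rho = rho, pValue = p, n = n)
}

#' Window effects paired with conversion-table sensible heat
#'
#' For every retained window: the potential cloud effect, the dominant
#' forest/non-forest land-cover pair, and the conversion-table
#' sensible-heat difference at the enclosing coarse cell. Windows whose
#' pair or table key is missing are dropped.
#'
#' @param classmap a [SurfaceClassMap-class].
#' @param landcover [GridField-class] of codes.
#' @param cloud multiyear mean cloud [GridField-class].
#' @param conversionTable data.frame as in [lookupDeltaH()].
#' @param elevation,waterBuffer,spec as in [potentialEffects()].
#' @param cellRes conversion-table cell size in degrees.
#' @return data.frame with `lat`, `lon`, `delta`, `deltaH`,
#'   `forestClass`, `nonforestClass`.
#' @export
heatLinkSamples <- function(classmap, landcover, cloud, conversionTable,
                            elevation = NULL, waterBuffer = NULL,
                            spec = windowSpec(), cellRes = 1) {
  windows <- placeWindows(classmap, spec)
  sam <- potentialEffects(classmap, cloud, elevation, waterBuffer, spec,
                          windows)
  if (!nrow(sam)) return(sam)
  wkey <- paste(windows$lat, windows$lon)
  skey <- paste(sam$lat, sam$lon)
  idx <- match(skey, wkey)
  rows <- lapply(seq_len(nrow(sam)), function(k) {
    pr <- dominantPair(classmap, landcover, windows$row0[idx[k]],
                       windows$col0[idx[k]], spec)
    if (!is.null(pr$reason)) return(NULL)
    dh <- lookupDeltaH(pr$forestClass, pr$nonforestClass, sam$lat[k],
                       sam$lon[k], conversionTable, cellRes)
    if (is.na(dh)) return(NULL)
    data.frame(lat = sam$lat[k], lon = sam$lon[k], delta = sam$delta[k],
               deltaH = dh, forestClass = pr$forestClass,
               nonforestClass = pr$nonforestClass)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(lat = numeric(), lon = numeric(),
                                      delta = numeric(), deltaH = numeric(),
                                      forestClass = integer(),
                                      nonforestClass = integer())
  out
}
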