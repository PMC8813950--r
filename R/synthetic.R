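.clip01 <- function(x) pmin(pmax(x, 0), 1)

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Build a scene configuration
#'
#' All arguments have defaults describing a mid-latitude 96 x 96-cell scene
#' at 0.05 degrees with a 2002-2018 cloud record; see [SceneConfig-class]
#' for the meaning and units of each parameter.
#'
#' @param nLat,nLon,resolution,originLat,originLon,years,seed scene frame.
#' @param b0,sTreeTrue,sTreeTrue2,sTreePattern,patchCount,patchSize,sEleTrue
#'   linear cloud model and its regional regimes.
#' @param noiseSdSpatial,noiseSdInterannual,correlationLength cloud noise.
#' @param eleMean,eleSd,eleCorrelationLength elevation model (m).
#' @param treeSd,treeCorrelationLength baseline tree-cover model.
#' @param lossPatchCount,lossPatchSize,lossRatePerYear forest-loss blobs.
#' @param waterFraction,wetlandFraction,snowLatMin,snowMonths masking model.
#' @param seasonalPeakMonth,seasonalAmplitude,diurnalPeakLocal timing model.
#' @param effectGrowthPerYear injected linear growth of the actual effect.
#' @param deltaHperSTree,deltaHNoiseSd sensible-heat conversion table model.
#' @param withHourly,withTypes generate the optional stacks.
#' @return a validated [SceneConfig-class].
#' @export
sceneConfig <- function(nLat = 96L, nLon = 96L, resolution = 0.05,
                        originLat = 40, originLon = 0,
                        years = 2002:2018, seed = 1L, b0 = 0.35,
                        sTreeTrue = 0.1, sTreeTrue2 = -0.1,
                        sTreePattern = "uniform", patchCount = 20L,
                        patchSize = 8L, sEleTrue = 5e-5,
                        noiseSdSpatial = 0.02, noiseSdInterannual = 0.01,
                        correlationLength = 3, eleMean = 300, eleSd = 50,
                        eleCorrelationLength = 8, treeSd = 0.35,
                        treeCorrelationLength = 6, lossPatchCount = 25L,
                        lossPatchSize = 40L, lossRatePerYear = 0.06,
                        waterFraction = 0.03, wetlandFraction = 0.01,
                        snowLatMin = 50, snowMonths = c(11L, 12L, 1L, 2L, 3L),
                        seasonalPeakMonth = 7L, seasonalAmplitude = 0.5,
                        diurnalPeakLocal = 14L, effectGrowthPerYear = 0,
                        deltaHperSTree = 400, deltaHNoiseSd = 5,
                        withHourly = FALSE, withTypes = FALSE) {
  new("SceneConfig", nLat = as.integer(nLat), nLon = as.integer(nLon),
      resolution = resolution, originLat = originLat, originLon = originLon,
      years = as.integer(years), seed = as.integer(seed), b0 = b0,
      sTreeTrue = sTreeTrue, sTreeTrue2 = sTreeTrue2,
      sTreePattern = sTreePattern, patchCount = as.integer(patchCount),
      patchSize = as.integer(patchSize), sEleTrue = sEleTrue,
      noiseSdSpatial = noiseSdSpatial, noiseSdInterannual = noiseSdInterannual,
      correlationLength = correlationLength, eleMean = eleMean, eleSd = eleSd,
      eleCorrelationLength = eleCorrelationLength, treeSd = treeSd,
      treeCorrelationLength = treeCorrelationLength,
      lossPatchCount = as.integer(lossPatchCount),
      lossPatchSize = as.integer(lossPatchSize),
      lossRatePerYear = lossRatePerYear, waterFraction = waterFraction,
      wetlandFraction = wetlandFraction, snowLatMin = snowLatMin,
      snowMonths = as.integer(snowMonths),
      seasonalPeakMonth = as.integer(seasonalPeakMonth),
      seasonalAmplitude = seasonalAmplitude,
      diurnalPeakLocal = as.integer(diurnalPeakLocal),
      effectGrowthPerYear = effectGrowthPerYear,
      deltaHperSTree = deltaHperSTree, deltaHNoiseSd = deltaHNoiseSd,
      withHourly = withHourly, withTypes = withTypes)
}

#' @rdname sceneConfig
#' @param config a [SceneConfig-class].
#' @export
configAsList <- function(config) {
  nm <- slotNames(config)
  stats::setNames(lapply(nm, function(s) slot(config, s)), nm)
}

#' Spatially correlated Gaussian random field
#'
#' White noise smoothed by circular convolution with a Gaussian kernel of
#' e-folding length `correlationLength` cells (via FFT), then recentred to
#' zero mean and rescaled to the requested sample standard deviation. With
#' `correlationLength = 0` the field is white; with `sd = 0` it is zero.
#' The same seed always reproduces the same field.
#'
#' @param shape integer length-2, `c(nLat, nLon)`.
#' @param correlationLength correlation length in cells (>= 0).
#' @param sd target standard deviation (>= 0).
#' @param seed optional integer seed (global RNG state is restored).
#' @param resolution,originLat,originLon geometry of the returned field.
#' @return a zero-mean [GridField-class] with sample s.d. exactly `sd`.
#' @export
generateRandomField <- function(shape, correlationLength, sd, seed = NULL,
                                resolution = 0.05, originLat = 0,
                                originLon = 0) {
  stopifnot(sd >= 0, correlationLength >= 0, length(shape) == 2L)
  n <- as.integer(shape[1]); p <- as.integer(shape[2])
  m <- .with_seed(seed, .correlated_noise(n, p, correlationLength, sd))
  gridField(m, resolution, originLat = originLat, originLon = originLon,
            variable = "noise", units = "1")
}

.correlated_noise <- function(n, p, L, sd) {
  if (sd == 0) return(matrix(0, n, p))
  z <- matrix(stats::rnorm(n * p), n, p)
  if (L > 0) {
    di <- pmin(0:(n - 1), n - 0:(n - 1))
    dj <- pmin(0:(p - 1), p - 0:(p - 1))
    kern <- exp(-outer(di^2, dj^2, "+") / (2 * L^2))
    # outer of squared distances: d2[i,j] = di^2 + dj^2
    z <- Re(stats::fft(stats::fft(z) * stats::fft(kern), inverse = TRUE)) / (n * p)
  }
  z <- z - mean(z)
  z * (sd / stats::sd(as.vector(z)))
}

.grow_patch <- function(allowed, seedCell, size) {
  # contiguous 4-neighbour blob grown breadth-first inside `allowed`
  n <- nrow(allowed); p <- ncol(allowed)
  inblob <- matrix(FALSE, n, p)
  queue <- seedCell
  inblob[seedCell[1], seedCell[2]] <- TRUE
  count <- 1L
  head <- 1L
  queue <- matrix(seedCell, ncol = 2)
  while (count < size && head <= nrow(queue)) {
    cur <- queue[head, ]; head <- head + 1L
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ni <- cur[1] + d[1]; nj <- cur[2] + d[2]
      if (ni >= 1 && ni <= n && nj >= 1 && nj <= p &&
          allowed[ni, nj] && !inblob[ni, nj]) {
        inblob[ni, nj] <- TRUE
        queue <- rbind(queue, c(ni, nj))
        count <- count + 1L
        if (count >= size) break
      }
    }
  }
  inblob
}

.s_tree_map <- function(cfg) {
  m <- matrix(cfg@sTreeTrue, cfg@nLat, cfg@nLon)
  if (cfg@sTreePattern == "halves") {
    m[, seq_len(cfg@nLon %/% 2)] <- cfg@sTreeTrue
    m[, (cfg@nLon %/% 2 + 1):cfg@nLon] <- cfg@sTreeTrue2
  } else if (cfg@sTreePattern == "patches") {
    for (k in seq_len(cfg@patchCount)) {
      i0 <- sample.int(cfg@nLat - cfg@patchSize + 1L, 1L)
      j0 <- sample.int(cfg@nLon - cfg@patchSize + 1L, 1L)
      m[i0:(i0 + cfg@patchSize - 1L), j0:(j0 + cfg@patchSize - 1L)] <- cfg@sTreeTrue2
    }
  }
  m
}

#' Generate a complete synthetic scene
#'
#' Draws every raster the pipeline consumes from the generative model in
#' [SceneConfig-class]: spatially correlated elevation and baseline tree
#' cover, contiguous forest-loss blobs with per-year loss rates, water from
#' the lowest elevations, an IGBP-style land-cover map, and cloud stacks
#' following the linear tree/elevation model with spatial plus interannual
#' noise, clipped to \[0, 1\], with snow-flagged months set nodata poleward
#' of `snowLatMin`. The whole scene is a deterministic function of
#' `config`, including its seed.
#'
#' @param config a [SceneConfig-class].
#' @return a [SyntheticScene-class].
#' @export
generateScene <- function(config) {
  cfg <- config
  validObject(cfg)
  .with_seed(cfg@seed, .generate_scene_impl(cfg))
}

.generate_scene_impl <- function(cfg) {
  n <- cfg@nLat; p <- cfg@nLon
  res <- cfg@resolution
  lat <- cfg@originLat + (seq_len(n) - 0.5) * res
  lon <- cfg@originLon + (seq_len(p) - 0.5) * res
  gf <- function(v, variable, units = "1", fraction = FALSE)
    gridField(v, res, lat = lat, lon = lon, variable = variable,
              units = units, fraction = fraction)

  elev <- pmax(cfg@eleMean +
               .correlated_noise(n, p, cfg@eleCorrelationLength, cfg@eleSd), 0)
  tree <- .clip01(0.5 + .correlated_noise(n, p, cfg@treeCorrelationLength,
                                          max(cfg@treeSd, 1e-12)))
  if (cfg@treeSd == 0) tree <- matrix(0.5, n, p) + tree * 0

  water <- matrix(0, n, p)
  if (cfg@waterFraction > 0) {
    k <- max(1L, round(cfg@waterFraction * n * p))
    water[order(elev)[seq_len(k)]] <- 1
  }
  tree[water == 1] <- 0

  lc <- matrix(LANDCOVER_CODES[["grassland"]], n, p)
  lc[tree < 0.25] <- LANDCOVER_CODES[["cropland"]]
  forest <- tree > 0.5
  southern <- row(lc) <= n %/% 2
  lc[forest & southern] <- LANDCOVER_CODES[["evergreen_broadleaf"]]
  lc[forest & !southern] <- LANDCOVER_CODES[["deciduous_broadleaf"]]
  if (cfg@wetlandFraction > 0) {
    cand <- which(water == 0 & !forest)
    k <- min(length(cand), max(1L, round(cfg@wetlandFraction * n * p)))
    wl <- sample(cand, k)
    lc[wl] <- LANDCOVER_CODES[["wetland"]]
  }
  lc[water == 1] <- LANDCOVER_CODES[["water"]]

  lossYears <- 2001:max(cfg@years)
  lossArr <- array(0, c(n, p, length(lossYears)))
  allowed <- forest & water == 0
  if (cfg@lossPatchCount > 0L) {
    if (!any(allowed))
      stop("loss patches requested but the scene has no forested area",
           call. = FALSE)
    seeds <- which(allowed)
    remaining <- tree
    for (k in seq_len(cfg@lossPatchCount)) {
      sc <- seeds[sample.int(length(seeds), 1L)]
      blob <- .grow_patch(allowed, c((sc - 1L) %% n + 1L, (sc - 1L) %/% n + 1L),
                          cfg@lossPatchSize)
      startYear <- sample(lossYears[seq_len(max(1L, length(lossYears) - 2L))], 1L)
      for (yi in seq_along(lossYears)) {
        if (lossYears[yi] < startYear) next
        take <- pmin(cfg@lossRatePerYear, remaining) * blob
        lossArr[, , yi] <- lossArr[, , yi] + take
        remaining <- remaining - take
      }
    }
  }
  gain <- matrix(0, n, p)

  sMap <- .s_tree_map(cfg)
  # spatially correlated noise is redrawn every year (weather), so the
  # multiyear mean tightens with record length; the interannual term is a
  # scene-wide scalar per year (large-scale variability)
  spatNoiseY <- lapply(seq_along(cfg@years), function(i)
    .correlated_noise(n, p, cfg@correlationLength, cfg@noiseSdSpatial))
  spatNoiseMean <- Reduce(`+`, spatNoiseY) / length(cfg@years)
  interNoise <- if (cfg@noiseSdInterannual > 0)
    stats::rnorm(length(cfg@years), 0, cfg@noiseSdInterannual) else
    numeric(length(cfg@years))

  cumLossTo <- function(year) {
    keep <- which(lossYears <= year)
    if (!length(keep)) matrix(0, n, p) else
      apply(lossArr[, , keep, drop = FALSE], c(1, 2), sum)
  }
  lossTotal <- cumLossTo(max(lossYears))
  lossMask <- (lossTotal > 0) + 0

  cloudY <- array(NA_real_, c(n, p, length(cfg@years)))
  for (yi in seq_along(cfg@years)) {
    y <- cfg@years[yi]
    treeY <- pmax(tree - cumLossTo(y) + gain, 0)
    cloudY[, , yi] <- .clip01(cfg@b0 + sMap * treeY + cfg@sEleTrue * elev +
                              spatNoiseY[[yi]] + interNoise[yi] +
                              cfg@effectGrowthPerYear * (y - min(cfg@years)) * lossMask)
  }

  treeMean <- pmax(tree - Reduce(`+`, lapply(cfg@years, cumLossTo)) /
                     length(cfg@years), 0)
  monthW <- 1 - cfg@seasonalAmplitude *
    (1 - cos(2 * pi * (1:12 - cfg@seasonalPeakMonth) / 12)) / 2
  cloudM <- array(NA_real_, c(n, p, 12))
  snowFlag <- array(FALSE, c(n, p, 12))
  for (m in 1:12) {
    cloudM[, , m] <- .clip01(cfg@b0 + monthW[m] * sMap * treeMean +
                             cfg@sEleTrue * elev + spatNoiseMean)
    if (m %in% cfg@snowMonths)
      snowFlag[, , m] <- matrix(lat >= cfg@snowLatMin, n, p)
  }
  monthly <- gridStack(cloudM, 1:12, "month", res, lat = lat, lon = lon,
                       variable = "cloud_fraction", fraction = TRUE)
  monthly <- maskSnow(monthly, snowFlag)

  hourly <- NULL
  if (cfg@withHourly) {
    cloudH <- array(NA_real_, c(n, p, 24))
    utcOffset <- round(lon / 15)
    for (h in 0:23) {
      localH <- (h + utcOffset) %% 24         # per-column local hour
      hd <- pmin(abs(localH - cfg@diurnalPeakLocal),
                 24 - abs(localH - cfg@diurnalPeakLocal))
      w <- exp(-hd^2 / (2 * 3^2))
      cloudH[, , h + 1] <- .clip01(cfg@b0 +
        sweep(sMap * treeMean, 2, w, `*`) + cfg@sEleTrue * elev + spatNoiseMean)
    }
    hourly <- gridStack(cloudH, 0:23, "hour", res, lat = lat, lon = lon,
                        variable = "cloud_fraction", fraction = TRUE)
  }

  types <- list()
  ctpF <- NULL; tauF <- NULL
  if (cfg@withTypes) {
    cloudTot <- apply(cloudY, c(1, 2), mean)
    gx <- cbind(abs(tree[, -1] - tree[, -p]), 0)
    gy <- rbind(abs(tree[-1, ] - tree[-n, ]), 0)
    grad <- pmax(gx, gy)
    steep <- grad > stats::quantile(grad, 0.5)
    # convective share of the cloud: surface-driven, rising with tree cover
    # (forest-triggered convection) and along tree-cover gradients where
    # mesoscale circulations form
    convShare <- pmin(0.35 + 0.3 * tree + 0.15 * steep, 0.9)
    weights <- matrix(0, 9, n * p)
    weights[8, ] <- 0.7 * convShare      # stratocumulus leads
    weights[3, ] <- 0.2 * convShare      # deep convection
    weights[7, ] <- 0.1 * convShare      # cumulus
    weights[1, ] <- 0.5 * (1 - convShare)
    weights[5, ] <- 0.3 * (1 - convShare)
    weights[2, ] <- 0.2 * (1 - convShare)
    types <- lapply(1:9, function(t)
      gf(matrix(weights[t, ] * as.vector(cloudTot), n, p),
         sprintf("cloud_fraction_type%d", t), fraction = TRUE))
    # representative retrievals consistent with the locally dominant type:
    # stratocumulus (low, medium tau) on steep gradients, cirrus elsewhere
    ctpF <- gf(matrix(ifelse(steep, 900, 300), n, p), "cloud_top_pressure", "hPa")
    tauF <- gf(matrix(ifelse(steep, 10, 1), n, p), "cloud_optical_depth", "1")
  }

  convTable <- .synthetic_conversion_table(cfg, sMap, lat, lon)

  new("SyntheticScene",
      elevation = gf(elev, "elevation", "m"),
      tree2000 = gf(tree, "tree_cover", "1", fraction = TRUE),
      yearlyLoss = gridStack(lossArr, lossYears, "year", res, lat = lat,
                             lon = lon, variable = "forest_loss",
                             fraction = TRUE),
      gain = gf(gain, "forest_gain", "1", fraction = TRUE),
      landcover = gf(lc + 0.0, "landcover", "code"),
      waterMask = gf(water, "water_mask", "1"),
      cloudYearly = gridStack(cloudY, cfg@years, "year", res, lat = lat,
                              lon = lon, variable = "cloud_fraction",
                              fraction = TRUE),
      cloudMonthly = monthly,
      cloudHourly = hourly,
      typeFractions = types,
      ctp = ctpF, tau = tauF,
      conversionTable = convTable,
      sTreeMap = gf(sMap, "s_tree_true", "cloud fraction per tree fraction"),
      config = cfg)
}

.coarse_bin <- function(coord, res) floor(coord / res)

.synthetic_conversion_table <- function(cfg, sMap, lat, lon) {
  binLat <- .coarse_bin(lat, 1)
  binLon <- .coarse_bin(lon, 1)
  cells <- unique(expand.grid(bLat = unique(binLat), bLon = unique(binLon)))
  forestClasses <- c(LANDCOVER_CODES[["evergreen_broadleaf"]],
                     LANDCOVER_CODES[["deciduous_broadleaf"]])
  nonforestClasses <- c(LANDCOVER_CODES[["grassland"]],
                        LANDCOVER_CODES[["cropland"]])
  rows <- list()
  for (r in seq_len(nrow(cells))) {
    inCell <- outer(binLat == cells$bLat[r], binLon == cells$bLon[r], `&`)
    sHere <- mean(sMap[inCell])
    for (fc in forestClasses) for (nc in nonforestClasses)
      rows[[length(rows) + 1L]] <- data.frame(
        cellLat = cells$bLat[r] + 0.5, cellLon = cells$bLon[r] + 0.5,
        forestClass = fc, nonforestClass = nc,
        deltaH = cfg@deltaHperSTree * sHere +
          stats::rnorm(1, 0, cfg@deltaHNoiseSd),
        provenance = "synthetic")
  }
  do.call(rbind, rows)
}

#' Small fixture scene for tests and examples
#'
#' A 64 x 64-cell, 5-year scene with reduced loss patches, generated in a
#' few hundredths of a second; deterministic in `seed`.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [sceneConfig()].
#' @export
fixtureScene <- function(seed = 1L, ...) {
  generateScene(sceneConfig(nLat = 64L, nLon = 64L, years = 2002:2006,
                            seed = seed, lossPatchCount = 12L,
                            lossPatchSize = 30L, lossRatePerYear = 0.08, ...))
}
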