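test_that("window placement covers the lattice and honours the change trigger", {
  cm <- toyClassmap()
  # a 9x9 grid holds exactly one window position
  small <- new("SurfaceClassMap",
               classes = matrix(CLASS_CODES[["UNCHANGED_FOREST"]], 9, 9),
               turnover = matrix(0.2, 9, 9), netChange = matrix(-0.2, 9, 9),
               lat = (1:9 - 0.5) * 0.05, lon = (1:9 - 0.5) * 0.05,
               resolution = 0.05)
  expect_equal(nrow(placeWindows(small)), 1L)

  w <- placeWindows(cm)
  expect_gt(nrow(w), 1)
  dr <- diff(sort(unique(w$centerRow)))
  expect_true(all(dr %% windowSpec()$step == 0))
  # all windows fully interior
  expect_true(all(w$row0 >= 1 & w$row0 + 8 <= 20))

  # brute-force scan oracle on a single changed pixel
  turn <- matrix(0, 20, 20); turn[7, 13] <- 0.2
  cm1 <- new("SurfaceClassMap", classes = matrix(CLASS_CODES[["UNCHANGED_FOREST"]], 20, 20),
             turnover = turn, netChange = -turn,
             lat = (1:20 - 0.5) * 0.05, lon = (1:20 - 0.5) * 0.05,
             resolution = 0.05)
  got <- placeWindows(cm1)
  oracle <- expand.grid(row0 = seq(1, 12, 5), col0 = seq(1, 12, 5))
  oracle <- oracle[vapply(seq_len(nrow(oracle)), function(k)
    7 >= oracle$row0[k] && 7 <= oracle$row0[k] + 8 &&
    13 >= oracle$col0[k] && 13 <= oracle$col0[k] + 8, logical(1)), ]
  expect_setequal(paste(got$row0, got$col0),
                  paste(oracle$row0, oracle$col0))

  tiny <- new("SurfaceClassMap", classes = matrix(CLASS_CODES[["MASKED"]], 5, 5),
              turnover = matrix(1, 5, 5), netChange = matrix(0, 5, 5),
              lat = (1:5) * 0.05, lon = (1:5) * 0.05, resolution = 0.05)
  expect_warning(out <- placeWindows(tiny), "smaller")
  expect_equal(nrow(out), 0L)
})

test_that("window class means match constant-field expectations and a loop oracle", {
  cm <- toyClassmap()
  cloudV <- matrix(0.5, 20, 20); cloudV[, 1:10] <- 0.6
  cloud <- gridField(cloudV, 0.05, originLat = 40, fraction = TRUE)
  sam <- potentialEffects(cm, cloud)
  expect_true(all(abs(sam$delta - 0.1) < 1e-12))

  flat <- gridField(matrix(0.42, 20, 20), 0.05, originLat = 40, fraction = TRUE)
  expect_true(all(potentialEffects(cm, flat)$delta == 0))

  set.seed(51)
  rv <- matrix(runif(400), 20, 20)
  rf <- gridField(rv, 0.05, originLat = 40, fraction = TRUE)
  w <- placeWindows(cm)
  sam2 <- potentialEffects(cm, rf, windows = w)
  wkey <- paste(w$lat, w$lon)
  for (k in seq_len(nrow(sam2))) {
    i <- match(paste(sam2$lat[k], sam2$lon[k]), wkey)
    o <- windowMeansOracle(gridValues(cm), rv, w$row0[i], w$col0[i], 9,
                           CLASS_CODES[["UNCHANGED_FOREST"]],
                           CLASS_CODES[["UNCHANGED_NONFOREST"]])
    expect_equal(sam2$meanForest[k], o$meanA, tolerance = 1e-12)
    expect_equal(sam2$meanNonforest[k], o$meanB, tolerance = 1e-12)
    expect_equal(sam2$nForest[k], o$nA)
    expect_equal(sam2$delta[k], o$meanA - o$meanB, tolerance = 1e-12)
  }
})

test_that("swapping the paired classes negates every delta exactly", {
  sc <- fix64()
  cm <- classifyScene(sc)
  cloud <- stackMean(sc@cloudYearly)
  ab <- classDeltaSamples(cm, cloud, CLASS_CODES[["UNCHANGED_FOREST"]],
                          CLASS_CODES[["UNCHANGED_NONFOREST"]])
  ba <- classDeltaSamples(cm, cloud, CLASS_CODES[["UNCHANGED_NONFOREST"]],
                          CLASS_CODES[["UNCHANGED_FOREST"]])
  expect_identical(ab$delta, -ba$delta)
})

test_that("the terrain filter applies the 100 m threshold and rejects whole windows", {
  spec <- windowSpec()
  expect_true(elevationFilter(matrix(300, 5, 5), spec))
  set.seed(52)
  rough <- matrix(rnorm(81, 300, 150), 9, 9)
  f <- elevationFilter(rough, spec)
  expect_identical(unclass(f)[1], sd(rough) <= 100)
  expect_equal(attr(f, "sd"), sd(rough))
  expect_false(elevationFilter(matrix(NA_real_, 3, 3), spec))

  cm <- toyClassmap()
  steep <- gridField(matrix(rnorm(400, 0, 200), 20, 20), 0.05, originLat = 40)
  cloud <- gridField(matrix(0.5, 20, 20), 0.05, originLat = 40, fraction = TRUE)
  sam <- potentialEffects(cm, cloud, elevation = steep)
  cnt <- attr(sam, "counts")
  expect_equal(cnt[["retained"]], 0L)
  expect_equal(cnt[["elevation_sd"]], cnt[["placed"]])
})

test_that("water-buffered pixels are excluded from both classes", {
  s <- toySurface(waterAt = cbind(5, 11))   # water just east of the divide
  cm <- toyClassmap(s)
  buf <- bufferWaterMask(s$water)
  set.seed(53)
  rv <- matrix(runif(400), 20, 20)
  rf <- gridField(rv, 0.05, originLat = 40, fraction = TRUE)
  w <- placeWindows(cm)
  sam <- potentialEffects(cm, rf, waterBuffer = buf, windows = w)
  wkey <- paste(w$lat, w$lon)
  for (k in seq_len(nrow(sam))) {
    i <- match(paste(sam$lat[k], sam$lon[k]), wkey)
    o <- windowMeansOracle(gridValues(cm), rv, w$row0[i], w$col0[i], 9,
                           CLASS_CODES[["UNCHANGED_FOREST"]],
                           CLASS_CODES[["UNCHANGED_NONFOREST"]], buffer = buf)
    expect_equal(sam$meanForest[k], o$meanA, tolerance = 1e-12)
    expect_equal(sam$meanNonforest[k], o$meanB, tolerance = 1e-12)
  }
})

test_that("the actual effect pairs loss with unchanged forest and rejects empty classes", {
  cm <- toyClassmap()
  cloudV <- matrix(0.5, 20, 20); cloudV[9:11, 8:10] <- 0.55
  cloud <- gridField(cloudV, 0.05, originLat = 40, fraction = TRUE)
  sam <- actualEffects(cm, cloud)
  expect_true(all(abs(sam$delta - 0.05) < 1e-12))
  # no loss pixels anywhere -> all windows rejected on the loss count
  noLoss <- gridValues(cm)
  noLoss[noLoss == CLASS_CODES[["FOREST_LOSS"]]] <- CLASS_CODES[["CHANGED_OTHER"]]
  cm2 <- new("SurfaceClassMap", classes = noLoss, turnover = cm@turnover,
             netChange = cm@netChange, lat = cm@lat, lon = cm@lon,
             resolution = cm@resolution)
  sam2 <- actualEffects(cm2, cloud)
  expect_equal(nrow(sam2), 0L)
  expect_equal(attr(sam2, "counts")[["min_count_a"]],
               attr(sam2, "counts")[["placed"]])
})

test_that("display binning is a half-open unweighted mean per cell", {
  one <- data.frame(lat = 40.1, lon = 0.2, delta = 0.03)
  em1 <- aggregateToDisplay(one, 0.5)
  expect_equal(gridValues(em1@delta)[1, 1], 0.03)
  expect_equal(latAxis(em1@delta), 40.25)

  two <- data.frame(lat = c(40.1, 40.3), lon = c(0.1, 0.4),
                    delta = c(-0.01, 0.03))
  expect_equal(gridValues(aggregateToDisplay(two, 0.5)@delta)[1, 1], 0.01)

  set.seed(54)
  many <- data.frame(lat = runif(100, -3, 3), lon = runif(100, 10, 16),
                     delta = rnorm(100))
  em <- aggregateToDisplay(many, 0.5)
  oracle <- binningOracle(many, 0.5)
  d <- em@delta
  for (key in names(oracle)) {
    ij <- as.integer(strsplit(key, " ")[[1]])
    i <- which(abs(latAxis(d) - (ij[1] + 0.5) * 0.5) < 1e-9)
    j <- which(abs(lonAxis(d) - (ij[2] + 0.5) * 0.5) < 1e-9)
    expect_equal(gridValues(d)[i, j], oracle[[key]])
  }
  expect_equal(sum(gridValues(em@count)), 100)
  expect_true(all(is.na(gridValues(d)[gridValues(em@count) == 0])))
})

test_that("sign fractions count zeros as enhancement and sum to 100", {
  pos <- gridField(matrix(abs(rnorm(16)) + 0.1, 4), 0.5)
  expect_equal(signFractions(pos), c(positive = 100, negative = 0))
  half <- gridField(matrix(c(1, -1), 4, 4), 0.5)
  expect_equal(signFractions(half), c(positive = 50, negative = 50))
  set.seed(55)
  v <- matrix(rnorm(100), 10); v[sample(100, 15)] <- NA
  f <- gridField(v, 0.5)
  sf <- signFractions(f)
  expect_equal(sf[["positive"]], 100 * sum(v >= 0, na.rm = TRUE) / sum(!is.na(v)))
  expect_equal(sum(sf), 100)
  withZero <- gridField(matrix(c(0, -1), 1, 2), 0.5)
  expect_equal(signFractions(withZero)[["positive"]], 50)
  expect_equal(signFractions(withZero, zeroAsPositive = FALSE)[["positive"]], 0)
})

test_that("latitudinal profiles split enhancement from inhibition per band", {
  set.seed(56)
  sam <- data.frame(lat = runif(200, 30, 36), lon = runif(200, 0, 3),
                    delta = rnorm(200, 0.005, 0.02))
  em <- aggregateToDisplay(sam, 0.5)
  prof <- latitudinalProfile(em, 1)
  v <- gridValues(em@delta)
  latCell <- matrix(latAxis(em@delta), nrow(v), ncol(v))
  for (r in seq_len(nrow(prof))) {
    inBand <- !is.na(v) & floor(latCell / 1) == prof$bandSouth[r]
    x <- v[inBand]
    if (any(x >= 0))
      expect_equal(prof$meanEnhancement[r], mean(x[x >= 0]))
    if (any(x < 0))
      expect_equal(prof$meanInhibition[r], mean(x[x < 0]))
    expect_equal(prof$nEnhancement[r] + prof$nInhibition[r], length(x))
  }
  allPos <- aggregateToDisplay(transform(sam, delta = abs(delta) + 0.01), 0.5)
  expect_true(all(is.na(latitudinalProfile(allPos, 1)$meanInhibition)))
})

test_that("seasonal and diurnal maxima follow the snow-free/local-time rules", {
  s <- c(0.01, 0.01, 0.02, 0.02, 0.03, 0.04, 0.05, 0.06, 0.09, 0.03, 0.02, 0.01)
  expect_equal(seasonalMaxMonth(s), 9L)
  # peak lands in a snow month: next-largest snow-free month is returned
  expect_equal(seasonalMaxMonth(s, snowfreeMonths = c(3:8, 10:12)), 8L)
  expect_equal(seasonalMaxMonth(rep(0.01, 12)), 1L)  # earliest on ties
  set.seed(57)
  for (rep in 1:20) {
    r <- rnorm(12); r[sample(12, 3)] <- NA
    free <- sort(sample(1:12, 8))
    got <- seasonalMaxMonth(r, free)
    cand <- intersect(free, which(!is.na(r)))
    if (length(cand))
      expect_equal(got, cand[which.max(abs(r[cand]))])
  }

  h <- rep(0, 24); h[13] <- 0.05          # UTC hour 12
  expect_equal(diurnalMaxHour(h, 30), 14L) # +2 h offset
  expect_equal(diurnalMaxHour(rep(0.01, 24), 0), 0L)
  for (rep in 1:20) {
    r <- rnorm(24)
    lon <- runif(1, -180, 180)
    off <- round(lon / 15)
    localSeries <- numeric(24)
    localSeries[((0:23 + off) %% 24) + 1] <- r
    expect_equal(diurnalMaxHour(r, lon),
                 as.integer(which.max(abs(localSeries)) - 1L))
  }
})
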