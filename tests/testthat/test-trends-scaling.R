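test_that("the annual tree-cover difference declines as loss accumulates", {
  n <- 12L
  tree <- matrix(0.8, n, n); tree[1:4, ] <- 0.7       # loss rows baseline 0.7
  lossSlice <- matrix(0, n, n); lossSlice[1:4, ] <- 0.05
  loss <- gridStack(list(lossSlice, lossSlice), 2001:2002, "year", 0.05,
                    fraction = TRUE)
  classes <- matrix(CLASS_CODES[["UNCHANGED_FOREST"]], n, n)
  classes[1:4, ] <- CLASS_CODES[["FOREST_LOSS"]]
  cm <- new("SurfaceClassMap", classes = classes,
            turnover = matrix(0, n, n), netChange = matrix(0, n, n),
            lat = (1:n - 0.5) * 0.05, lon = (1:n - 0.5) * 0.05,
            resolution = 0.05)
  tr <- gridField(tree, 0.05, fraction = TRUE)
  dts <- deltaTreeSeries(cm, tr, loss, years = 2001:2002)
  expect_equal(dts$deltaTree[1], -0.1 - 0.05)
  expect_equal(dts$deltaTree[2], -0.1 - 0.10)

  # no loss anywhere: the series is the constant baseline difference
  zero <- gridStack(list(matrix(0, n, n)), 2001, "year", 0.05, fraction = TRUE)
  flat <- deltaTreeSeries(cm, tr, zero, years = 2001)
  expect_equal(flat$deltaTree, -0.1)

  # random loss schedules against a cumulative-sum oracle
  set.seed(81)
  slices <- replicate(5, matrix(runif(n * n, 0, 0.02), n, n), simplify = FALSE)
  rl <- gridStack(slices, 2001:2005, "year", 0.05, fraction = TRUE)
  got <- deltaTreeSeries(cm, tr, rl, years = 2001:2005)
  isL <- classes == CLASS_CODES[["FOREST_LOSS"]]
  isF <- classes == CLASS_CODES[["UNCHANGED_FOREST"]]
  acc <- 0
  for (k in 1:5) {
    acc <- acc + (mean(slices[[k]][isL]) - mean(slices[[k]][isF]))
    expect_equal(got$deltaTree[k],
                 (mean(tree[isL]) - mean(tree[isF])) - acc)
  }
  noLossClasses <- cm
  noLossClasses@classes[] <- CLASS_CODES[["UNCHANGED_FOREST"]]
  expect_error(deltaTreeSeries(noLossClasses, tr, rl), "required")
})

test_that("trend fitting reproduces printed trend-to-total arithmetic and an OLS oracle", {
  years <- 2002:2018
  exact <- data.frame(year = years, delta = 0.00046 * (years - 2001))
  tr <- fitTrend(exact)
  expect_equal(tr$slope, 0.046, tolerance = 1e-10)
  expect_equal(tr$totalChange, 0.782, tolerance = 1e-10)
  expect_equal(tr$totalChange / tr$slope, 17)

  const <- data.frame(year = years, delta = rep(0.01, 17))
  trc <- fitTrend(const)
  expect_equal(trc$slope, 0, tolerance = 1e-12)
  expect_equal(trc$totalChange, 0, tolerance = 1e-12)
  expect_true(is.na(trc$pValue))

  set.seed(82)
  noisy <- data.frame(year = years,
                      delta = 0.0005 * (years - 2001) + rnorm(17, 0, 0.002))
  trn <- fitTrend(noisy)
  o <- olsSlopeOracle(years, noisy$delta * 100)
  expect_equal(trn$slope, o$slope, tolerance = 1e-8)
  expect_equal(trn$intercept, o$intercept, tolerance = 1e-8)
  expect_equal(trn$pValue, o$p, tolerance = 1e-8)
})

test_that("annual effect series averages qualifying display cells and matches a loop oracle", {
  sc <- fix64()
  cm <- classifyScene(sc)
  buf <- bufferWaterMask(sc@waterMask)
  ser <- annualEffectSeries(sc@cloudYearly, cm, sc@yearlyLoss,
                            elevation = sc@elevation, waterBuffer = buf)
  expect_equal(ser$year, timeAxis(sc@cloudYearly))
  expect_true(all(ser$n > 0))
  # independent per-year oracle: rebuild the yearly means and re-bin by hand
  totalLoss <- apply(gridValues(sc@yearlyLoss), c(1, 2), sum)
  latv <- rep(latAxis(cm), times = length(lonAxis(cm)))
  lonv <- rep(lonAxis(cm), each = length(latAxis(cm)))
  key <- paste(floor(latv / 0.5), floor(lonv / 0.5))
  lossFrac <- tapply(as.vector(totalLoss), key, mean)
  for (y in ser$year[c(1, 3)]) {
    sam <- actualEffects(cm, getSlice(sc@cloudYearly, y), sc@elevation, buf)
    cellVals <- binningOracle(sam, 0.5)
    keep <- names(cellVals)[lossFrac[names(cellVals)] > 0.05]
    expect_equal(ser$delta[ser$year == y], mean(cellVals[keep]))
  }
  # a region that excludes every loss cell is an error
  expect_error(annualEffectSeries(sc@cloudYearly, cm, sc@yearlyLoss,
                                  region = c(lonMin = 100, lonMax = 110,
                                             latMin = -50, latMax = -40),
                                  elevation = sc@elevation, waterBuffer = buf),
               "qualify")
})

test_that("injected linear effect growth is recovered by the trend fit", {
  g <- 0.002
  slopes <- vapply(c(83L, 84L, 85L), function(s) {
    sc <- generateScene(sceneConfig(sTreeTrue = 0, sTreeTrue2 = 0,
                                    sEleTrue = 0, effectGrowthPerYear = g,
                                    seed = s))
    cm <- classifyScene(sc)
    ser <- annualEffectSeries(sc@cloudYearly, cm, sc@yearlyLoss,
                              elevation = sc@elevation,
                              waterBuffer = bufferWaterMask(sc@waterMask))
    tr <- fitTrend(ser)
    expect_lt(tr$pValue, 0.01)
    tr$slope
  }, 0)
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 100 * g), 2 * se)
})

test_that("the potential and actual effects have opposite signs on one-regime scenes", {
  sc <- fix64()
  cm <- classifyScene(sc)
  buf <- bufferWaterMask(sc@waterMask)
  cloud <- stackMean(sc@cloudYearly)
  pot <- potentialEffects(cm, cloud, sc@elevation, buf)
  act <- actualEffects(cm, cloud, sc@elevation, buf)
  expect_gt(mean(pot$delta), 0)   # enhancement regime (S_tree > 0)
  expect_lt(mean(act$delta), 0)   # loss moves the surface toward non-forest
})

test_that("the scale experiment is deterministic and keeps sign-pure scenes pure", {
  sc <- cachedScene("scale_pure", function()
    generateScene(sceneConfig(nLat = 120L, nLon = 120L, lossPatchCount = 45L,
                              lossPatchSize = 60L, lossRatePerYear = 0.08,
                              noiseSdSpatial = 0.005, seed = 84L)))
  cfgs <- scaleConfigs()[c(1, 3, 5), ]
  t1 <- rescaleExperiment(sc, cfgs)
  t2 <- rescaleExperiment(sc, cfgs)
  expect_identical(t1, t2)
  with_samples <- t1[t1$nSamples > 0, ]
  expect_gt(nrow(with_samples), 0)
  expect_true(all(with_samples$positive > 95))
  expect_error(rescaleExperiment(sc, data.frame(resolution = 0.07,
                                                windowSize = 3L, step = 1L,
                                                displayRes = 0.5)),
               "integer multiple")
})
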