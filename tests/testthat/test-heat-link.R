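test_that("dominant land-cover pairs are modal per class with smallest-code ties", {
  s <- toySurface()
  cm <- toyClassmap(s)
  pr <- dominantPair(cm, s$landcover, 1L, 6L)
  expect_equal(pr$forestClass, unname(LANDCOVER_CODES[["evergreen_broadleaf"]]))
  expect_equal(pr$nonforestClass, unname(LANDCOVER_CODES[["grassland"]]))

  # mixed non-forest: 3 cropland vs fewer grassland pixels -> cropland
  lc2 <- gridValues(s$landcover)
  lc2[, 11:20] <- LANDCOVER_CODES[["cropland"]]
  lc2[1, 11] <- LANDCOVER_CODES[["grassland"]]
  pr2 <- dominantPair(cm, gridField(lc2, 0.05, originLat = 40), 1L, 6L)
  expect_equal(pr2$nonforestClass, unname(LANDCOVER_CODES[["cropland"]]))

  # no non-forest pixels inside the window -> rejection
  pr3 <- dominantPair(cm, s$landcover, 1L, 1L)
  expect_equal(pr3$reason, "empty_class")

  set.seed(91)
  lcR <- matrix(sample(c(2, 4, 10, 12), 400, replace = TRUE), 20, 20)
  pr4 <- dominantPair(cm, gridField(lcR, 0.05, originLat = 40), 6L, 6L)
  cl <- gridValues(cm)[6:14, 6:14]
  blk <- lcR[6:14, 6:14]
  oracleModal <- function(x) {
    tab <- table(x)
    as.numeric(names(tab)[tab == max(tab)][1])
  }
  expect_equal(pr4$forestClass,
               oracleModal(blk[cl == CLASS_CODES[["UNCHANGED_FOREST"]]]))
  expect_equal(pr4$nonforestClass,
               oracleModal(blk[cl == CLASS_CODES[["UNCHANGED_NONFOREST"]]]))
})

test_that("conversion-table lookups are exact-key with typed missing values", {
  tab <- data.frame(cellLat = c(40.5, 40.5), cellLon = c(0.5, 1.5),
                    forestClass = c(2L, 2L), nonforestClass = c(12L, 12L),
                    deltaH = c(12.5, -3))
  expect_equal(lookupDeltaH(2, 12, 40.2, 0.9, tab), 12.5)
  expect_equal(lookupDeltaH(2, 12, 40.9, 1.1, tab), -3)
  expect_true(is.na(lookupDeltaH(4, 12, 40.2, 0.9, tab)))   # absent key
  expect_true(is.na(lookupDeltaH(2, 12, 42.2, 0.9, tab)))   # absent cell
  set.seed(92)
  rt <- data.frame(cellLat = sample(seq(-9.5, 9.5), 30, TRUE),
                   cellLon = sample(seq(-9.5, 9.5), 30, TRUE),
                   forestClass = sample(c(2L, 4L), 30, TRUE),
                   nonforestClass = sample(c(10L, 12L), 30, TRUE),
                   deltaH = rnorm(30, 0, 30))
  for (k in sample(30, 8)) {
    got <- lookupDeltaH(rt$forestClass[k], rt$nonforestClass[k],
                        rt$cellLat[k], rt$cellLon[k], rt)
    scan <- NA_real_
    for (r in seq_len(nrow(rt)))
      if (rt$cellLat[r] == rt$cellLat[k] && rt$cellLon[r] == rt$cellLon[k] &&
          rt$forestClass[r] == rt$forestClass[k] &&
          rt$nonforestClass[r] == rt$nonforestClass[k]) { scan <- rt$deltaH[r]; break }
    expect_equal(got, scan)
  }
})

test_that("the daytime mean covers local hours 8 through 16 inclusive", {
  expect_equal(daytimeMeanH(rep(100, 24)), 100)
  h <- rep(0, 24); h[21] <- 500   # hour 20, outside the daytime window
  expect_equal(daytimeMeanH(h), 0)
  set.seed(93)
  r <- rnorm(24, 100, 30)
  expect_equal(daytimeMeanH(r), mean(r[9:17]))
})

test_that("site pairs read the midpoint cell and apply the exclusion rules", {
  d <- matrix(NA_real_, 4, 4)
  d[2, 2] <- 0.03
  em <- new("EffectMap",
            delta = gridField(d, 1, originLat = 40, originLon = 0),
            count = gridField((!is.na(d)) + 0, 1, originLat = 40, originLon = 0))
  pairs <- data.frame(latForest = c(41.2, 41.2, 43.5),
                      lonForest = c(1.2, 1.2, 3.5),
                      latNonforest = c(41.8, 41.8, 43.6),
                      lonNonforest = c(1.8, 1.8, 3.6),
                      deltaH = c(40, 250, 40))
  got <- matchSitePairs(pairs, em)
  expect_equal(got$deltaCloud[1], 0.03)   # same cell midpoint
  expect_false(got$excluded[1])
  expect_true(got$excluded[2])            # deltaH > 200 W/m2
  expect_equal(got$reason[2], "deltaH outlier")
  expect_true(got$excluded[3])            # midpoint on a nodata cell
  expect_equal(got$reason[3], "missing deltaCloud")
  # exclusion never alters the stored values
  expect_equal(got$deltaH, pairs$deltaH)
})

test_that("geometric mean regression has the closed form and axis symmetry", {
  x <- c(1, 2, 3, 4, 5)
  g <- gmRegression(x, 2 * x)
  expect_equal(g$slope, 2, tolerance = 1e-12)
  expect_equal(g$intercept, 0, tolerance = 1e-12)
  g2 <- gmRegression(x, -x + 3)
  expect_equal(g2$slope, -1, tolerance = 1e-12)
  expect_equal(g2$intercept, 3, tolerance = 1e-12)
  set.seed(94)
  xn <- rnorm(60); yn <- 0.4 * xn + rnorm(60, 0, 0.5)
  gn <- gmRegression(xn, yn)
  expect_equal(gn$slope, sign(cor(xn, yn)) * sd(yn) / sd(xn), tolerance = 1e-12)
  gyx <- gmRegression(yn, xn)
  expect_equal(gn$slope * gyx$slope, 1, tolerance = 1e-12)
  expect_error(gmRegression(x, rep(1, 5)), "variance")
})

test_that("rank correlation handles monotone data, ties, and the t-approximation p", {
  expect_equal(rankCorrelation(1:10, (1:10)^3)$rho, 1)
  expect_equal(rankCorrelation(1:10, -(1:10))$rho, -1)
  expect_equal(rankCorrelation(1:10, (1:10)^3)$pValue, 0)
  x <- c(1, 2, 2, 3, 5, 5, 5, 8)
  y <- c(2, 1, 4, 4, 6, 9, 7, 8)
  got <- rankCorrelation(x, y)
  rho <- cor(rank(x), rank(y))
  expect_equal(got$rho, rho)
  expect_equal(got$rho, cor(x, y, method = "spearman"))
  tstat <- rho * sqrt((8 - 2) / (1 - rho^2))
  expect_equal(got$pValue, 2 * pt(-abs(tstat), 6), tolerance = 1e-12)
})

test_that("table-driven sensible heat tracks the window effect sign across regimes", {
  sc <- cachedScene("heat_halves", function()
    generateScene(sceneConfig(nLat = 128L, nLon = 128L, sTreePattern = "halves",
                              lossPatchCount = 45L, seed = 5L)))
  cm <- classifyScene(sc)
  hs <- heatLinkSamples(cm, sc@landcover, stackMean(sc@cloudYearly),
                        sc@conversionTable, sc@elevation,
                        bufferWaterMask(sc@waterMask))
  expect_gte(nrow(hs), 50)
  rc <- rankCorrelation(hs$deltaH, hs$delta)
  expect_gt(rc$rho, 0.5)
  expect_lt(rc$pValue, 1e-6)
  # entries agree with direct lookups (pure filtering, no value changes)
  for (k in sample(nrow(hs), 5))
    expect_equal(hs$deltaH[k],
                 lookupDeltaH(hs$forestClass[k], hs$nonforestClass[k],
                              hs$lat[k], hs$lon[k], sc@conversionTable))
})
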