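# scenes are expensive enough to share across tests; cache per test run
.scene_cache <- new.env(parent = emptyenv())

cachedScene <- function(key, maker) {
  if (!exists(key, .scene_cache)) assign(key, maker(), .scene_cache)
  get(key, .scene_cache)
}

fix64 <- function() cachedScene("fix64", function() fixtureScene(seed = 11L))

fixNoiseFree <- function() cachedScene("noisefree", function()
  generateScene(sceneConfig(noiseSdSpatial = 0, noiseSdInterannual = 0,
                            seed = 3L)))

fixTypes <- function() cachedScene("types", function()
  generateScene(sceneConfig(nLat = 64L, nLon = 64L, years = 2002:2006,
                            lossPatchCount = 12L, lossPatchSize = 30L,
                            lossRatePerYear = 0.08, withTypes = TRUE,
                            seed = 4L)))

# a hand-built 20 x 20 surface: west half forest, east half grassland,
# a 3 x 3 loss block and a known turnover pattern to trigger windows
toySurface <- function(waterAt = NULL) {
  n <- 20L
  tree <- matrix(0.3, n, n); tree[, 1:10] <- 0.8
  lc <- matrix(LANDCOVER_CODES[["grassland"]], n, n)
  lc[, 1:10] <- LANDCOVER_CODES[["evergreen_broadleaf"]]
  lossSlice <- matrix(0, n, n)
  lossSlice[9:11, 8:10] <- 0.1   # 0.2 accumulated over two years
  loss <- gridStack(list(lossSlice, lossSlice), time = 2001:2002,
                    timeUnit = "year", resolution = 0.05, originLat = 40,
                    originLon = 0, variable = "forest_loss", fraction = TRUE)
  mk <- function(v, var, frac = FALSE)
    gridField(v, 0.05, originLat = 40, originLon = 0, variable = var,
              fraction = frac)
  water <- matrix(0, n, n)
  if (!is.null(waterAt)) water[waterAt] <- 1
  list(tree2000 = mk(tree, "tree_cover", TRUE),
       yearlyLoss = loss,
       gain = mk(matrix(0, n, n), "forest_gain", TRUE),
       landcover = mk(lc + 0.0, "landcover"),
       water = mk(water, "water_mask"),
       elevation = mk(matrix(250, n, n), "elevation"))
}

toyClassmap <- function(s = toySurface()) {
  ch <- computeChange(s$tree2000, s$yearlyLoss, s$gain)
  classifyPixels(s$tree2000, ch$turnover, ch$netChange, s$landcover)
}
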