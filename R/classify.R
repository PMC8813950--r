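#' Classifier configuration
#'
#' Thresholds of the per-pixel land-state classification. A pixel is
#' unchanged when its forest-change measure stays below `changeThreshold`
#' (0.05); it is forest loss when its net loss (accumulated loss minus
#' gain) exceeds `lossThreshold` (0.15). Forest vs non-forest splits at a
#' baseline tree-cover fraction of `forestThreshold` (0.5, strict `>` for
#' forest, so exactly 0.5 is non-forest). `unchangedMetric` selects the
#' change measure: `"turnover"` (gross, accumulated loss + gain; default —
#' a pixel with loss = gain = 0.2 is genuinely disturbed) or `"signed"`
#' (|gain - loss|). Non-forest pixels whose land cover is water, snow/ice
#' or wetland are excluded from the unchanged non-forest pool.
#'
#' @param forestThreshold,changeThreshold,lossThreshold fractions in (0, 1).
#' @param excludedNonforest integer land-cover codes excluded from
#'   UNCHANGED_NONFOREST.
#' @param unchangedMetric `"turnover"` or `"signed"`; also governs the
#'   window-placement change trigger.
#' @return a list of class `ClassifierConfig`.
#' @export
classifierConfig <- function(forestThreshold = 0.5, changeThreshold = 0.05,
                             lossThreshold = 0.15,
                             excludedNonforest = unname(LANDCOVER_CODES[
                               c("water", "snow_ice", "wetland")]),
                             unchangedMetric = c("turnover", "signed")) {
  stopifnot(forestThreshold > 0, forestThreshold < 1,
            changeThreshold > 0, changeThreshold < 1,
            lossThreshold >= changeThreshold, lossThreshold < 1)
  structure(list(forestThreshold = forestThreshold,
                 changeThreshold = changeThreshold,
                 lossThreshold = lossThreshold,
                 excludedNonforest = as.integer(excludedNonforest),
                 unchangedMetric = match.arg(unchangedMetric)),
            class = "ClassifierConfig")
}

#' Accumulated forest-cover change
#'
#' From the baseline tree cover, the yearly loss stack and the gain field,
#' computes the gross turnover (accumulated loss + gain; the magnitude of
#' disturbance) and the signed net change (gain - accumulated loss; net
#' loss is its negation).
#'
#' @param tree2000 baseline tree-cover [GridField-class].
#' @param yearlyLoss [GridStack-class] of per-year loss fractions.
#' @param gain [GridField-class] of gain fraction.
#' @return list with [GridField-class] elements `turnover` and `netChange`.
#' @export
computeChange <- function(tree2000, yearlyLoss, gain) {
  .stop_geometry(tree2000, yearlyLoss, "tree2000 vs yearlyLoss")
  .stop_geometry(tree2000, gain, "tree2000 vs gain")
  totalLoss <- apply(yearlyLoss@values, c(1, 2), sum)
  g <- gain@values
  mk <- function(v, name) gridField(v, tree2000@resolution,
                                    lat = tree2000@lat, lon = tree2000@lon,
                                    variable = name)
  list(turnover = mk(totalLoss + g, "turnover"),
       netChange = mk(g - totalLoss, "net_change"))
}

#' Classify pixels into land states
#'
#' UNCHANGED_FOREST: baseline tree cover > 0.5 and change < 0.05.
#' UNCHANGED_NONFOREST: tree cover < 0.5 (or equal), change < 0.05 and land
#' cover not water/snow-ice/wetland. FOREST_LOSS: net loss > 0.15.
#' Everything else CHANGED_OTHER; nodata inputs MASKED. The classification
#' is a pure per-pixel function, independent of visiting order.
#'
#' @param tree2000,turnover,netChange,landcover aligned [GridField-class]s
#'   (`landcover` holds integer codes).
#' @param config a [classifierConfig()].
#' @return a [SurfaceClassMap-class].
#' @export
classifyPixels <- function(tree2000, turnover, netChange, landcover,
                           config = classifierConfig()) {
  .stop_geometry(tree2000, turnover, "tree2000 vs turnover")
  .stop_geometry(tree2000, netChange, "tree2000 vs netChange")
  .stop_geometry(tree2000, landcover, "tree2000 vs landcover")
  tv <- tree2000@values; to <- turnover@values
  nc <- netChange@values; lc <- landcover@values
  change <- if (config$unchangedMetric == "turnover") to else abs(nc)
  netLoss <- -nc
  cl <- matrix(CLASS_CODES[["CHANGED_OTHER"]], nrow(tv), ncol(tv))
  unchanged <- change < config$changeThreshold
  cl[unchanged & tv > config$forestThreshold] <- CLASS_CODES[["UNCHANGED_FOREST"]]
  cl[unchanged & tv <= config$forestThreshold &
       !(lc %in% config$excludedNonforest)] <- CLASS_CODES[["UNCHANGED_NONFOREST"]]
  cl[netLoss > config$lossThreshold] <- CLASS_CODES[["FOREST_LOSS"]]
  cl[is.na(tv) | is.na(to) | is.na(nc) | is.na(lc)] <- CLASS_CODES[["MASKED"]]
  new("SurfaceClassMap", classes = cl, turnover = to, netChange = nc,
      lat = tree2000@lat, lon = tree2000@lon,
      resolution = tree2000@resolution)
}

#' Classify a synthetic scene in one call
#'
#' Convenience wrapper: [computeChange()] then [classifyPixels()].
#'
#' @param scene a [SyntheticScene-class].
#' @param config a [classifierConfig()].
#' @export
classifyScene <- function(scene, config = classifierConfig()) {
  ch <- computeChange(scene@tree2000, scene@yearlyLoss, scene@gain)
  classifyPixels(scene@tree2000, ch$turnover, ch$netChange, scene@landcover,
                 config)
}

#' One-pixel water buffer
#'
#' Marks water pixels and all their 8-neighbours (a morphological dilation
#' with a 3 x 3 structuring element); buffered pixels are excluded from
#' both window classes so shoreline cloud signals do not contaminate the
#' forest/non-forest contrast.
#'
#' @param waterMask a [GridField-class] (nonzero = water) or logical matrix.
#' @return logical matrix, `TRUE` at buffered pixels.
#' @export
bufferWaterMask <- function(waterMask) {
  w <- if (is(waterMask, "GridField")) waterMask@values else waterMask
  w <- !is.na(w) & w != 0
  n <- nrow(w); p <- ncol(w)
  out <- matrix(FALSE, n, p)
  for (di in -1:1) for (dj in -1:1) {
    src_r <- max(1, 1 - di):min(n, n - di)
    src_c <- max(1, 1 - dj):min(p, p - dj)
    out[src_r + di, src_c + dj] <- out[src_r + di, src_c + dj] | w[src_r, src_c]
  }
  out
}

#' Mask snow-flagged observations out of a cloud stack
#'
#' Sets cloud values to nodata exactly where the per-slice snow flag is
#' set (snow degrades cloud detection); all other values are untouched.
#'
#' @param cloudStack a [GridStack-class].
#' @param snowFlags logical array with the stack's dimensions, or a
#'   [GridStack-class] of 0/1 flags.
#' @return the masked [GridStack-class].
#' @export
maskSnow <- function(cloudStack, snowFlags) {
  fl <- if (is(snowFlags, "GridStack")) snowFlags@values != 0 else snowFlags
  stopifnot(identical(dim(fl), dim(cloudStack@values)))
  v <- cloudStack@values
  v[fl] <- NA_real_
  initialize(cloudStack, values = v)
}
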