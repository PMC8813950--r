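#' Attribution class codes
#'
#' Tree-cover induced cloud increase/decrease, orography induced cloud
#' increase/decrease, and unexplained effects.
#' @export
ATTRIBUTION_CODES <- c(TREE_PLUS = 1L, TREE_MINUS = 2L, ORO_PLUS = 3L,
                       ORO_MINUS = 4L, OTHER = 5L)

#' Per-window sensitivities of cloud to tree cover and elevation
#'
#' Ordinary least squares of cloud fraction on tree cover, elevation and
#' an intercept over the pixels of one window:
#' `cloud = S_tree * tree + S_ele * elevation + c`. Requires at least 4
#' valid pixels, a nonzero tree cover somewhere in the window, and a
#' full-rank design (constant elevation is rejected with a reason code).
#'
#' @param cloud,tree,elevation numeric vectors over window pixels.
#' @return list with `sTree`, `sEle`, `c`, `n`; or, on rejection, a list
#'   with a single `reason` element (`"too_few_pixels"`, `"zero_tree"`,
#'   `"rank_deficient"`).
#' @export
fitWindowSensitivities <- function(cloud, tree, elevation) {
  ok <- !(is.na(cloud) | is.na(tree) | is.na(elevation))
  cloud <- cloud[ok]; tree <- tree[ok]; elevation <- elevation[ok]
  if (length(cloud) < 4L) return(list(reason = "too_few_pixels"))
  if (all(tree == 0)) return(list(reason = "zero_tree"))
  X <- cbind(1, tree, elevation)
  fit <- stats::lm.fit(X, cloud)
  if (fit$rank < 3L) return(list(reason = "rank_deficient"))
  cf <- unname(fit$coefficients)
  list(sTree = cf[2], sEle = cf[3], c = cf[1], n = length(cloud))
}

#' Decompose a window effect into tree and orography terms
#'
#' `dCloudTree = sTree * dTree`, `dCloudEle = sEle * dEle` — the cloud
#' differences induced by the tree-cover and elevation differences between
#' the paired window classes.
#'
#' @param sTree,sEle sensitivities (vectorized).
#' @param dTree,dEle forest-minus-non-forest differences.
#' @return data.frame with `dCloudTree`, `dCloudEle`.
#' @export
decomposeEffect <- function(sTree, sEle, dTree, dEle) {
  data.frame(dCloudTree = sTree * dTree, dCloudEle = sEle * dEle)
}

#' Classify the dominant attribution factor
#'
#' If both components share the sign of the total effect, the larger
#' magnitude dominates (exact ties go to tree cover, the driver of
#' interest); if exactly one shares the sign, it dominates; if neither
#' does — or the total effect is exactly zero — the cell is OTHER. The
#' sign of the total effect sets the +/- suffix.
#'
#' @param dCloud,dCloudTree,dCloudEle numeric vectors.
#' @return integer vector of [ATTRIBUTION_CODES].
#' @export
classifyAttribution <- function(dCloud, dCloudTree, dCloudEle) {
  out <- rep(ATTRIBUTION_CODES[["OTHER"]], length(dCloud))
  sgn <- sign(dCloud)
  sameT <- !is.na(dCloudTree) & sign(dCloudTree) == sgn & sgn != 0
  sameE <- !is.na(dCloudEle) & sign(dCloudEle) == sgn & sgn != 0
  treeDom <- (sameT & !sameE) |
    (sameT & sameE & abs(dCloudTree) >= abs(dCloudEle))
  eleDom <- (sameE & !sameT) |
    (sameT & sameE & abs(dCloudEle) > abs(dCloudTree))
  out[treeDom & sgn > 0] <- ATTRIBUTION_CODES[["TREE_PLUS"]]
  out[treeDom & sgn < 0] <- ATTRIBUTION_CODES[["TREE_MINUS"]]
  out[eleDom & sgn > 0] <- ATTRIBUTION_CODES[["ORO_PLUS"]]
  out[eleDom & sgn < 0] <- ATTRIBUTION_CODES[["ORO_MINUS"]]
  out[is.na(dCloud)] <- NA_integer_
  out
}

#' Fraction of the effect explained by the reconstruction
#'
#' How much of the original window effect the sum
#' `dCloudTree + dCloudEle` reproduces. Default metric is the coefficient
#' of determination (squared Pearson correlation of original vs
#' reconstructed); `"abs_ratio"` gives the magnitude ratio
#' `sum(|reconstructed|) / sum(|original|)` instead.
#'
#' @param original,reconstructed paired numeric vectors, n >= 3.
#' @param method `"r2"` or `"abs_ratio"`.
#' @return a single fraction.
#' @export
reconstructionExplained <- function(original, reconstructed,
                                    method = c("r2", "abs_ratio")) {
  method <- match.arg(method)
  ok <- !(is.na(original) | is.na(reconstructed))
  original <- original[ok]; reconstructed <- reconstructed[ok]
  stopifnot(length(original) >= 3L)
  if (method == "abs_ratio") return(sum(abs(reconstructed)) / sum(abs(original)))
  if (stats::sd(original) == 0 || stats::sd(reconstructed) == 0) {
    # degenerate: identical constants explain perfectly, otherwise nothing
    return(if (isTRUE(all.equal(original, reconstructed))) 1 else 0)
  }
  stats::cor(original, reconstructed)^2
}

#' Full attribution of window effects
#'
#' Runs the window estimator for cloud, tree-cover and elevation
#' differences, fits the per-window sensitivities, averages sensitivities
#' and differences to the display grid, and only then forms the
#' decomposition and the five-class attribution per display cell.
#'
#' @param classmap a [SurfaceClassMap-class].
#' @param cloud,tree,elevation [GridField-class]s: multiyear mean cloud
#'   fraction, mean tree-cover fraction, and elevation.
#' @param waterBuffer optional logical matrix from [bufferWaterMask()].
#' @param spec a [windowSpec()].
#' @param displayRes display grid resolution in degrees.
#' @return list with `windows` (per-window samples: delta, dTree, dEle,
#'   sTree, sEle), `cells` (per display cell: averaged terms, the
#'   decomposition, `class`), `explained` (R2 of original vs reconstructed
#'   over cells) and `classShares` (percent per attribution class).
#' @export
attributeEffects <- function(classmap, cloud, tree, elevation,
                             waterBuffer = NULL, spec = windowSpec(),
                             displayRes = 0.5) {
  windows <- placeWindows(classmap, spec)
  dCloud <- potentialEffects(classmap, cloud, elevation, waterBuffer, spec,
                             windows)
  dTree <- potentialEffects(classmap, tree, elevation, waterBuffer, spec,
                            windows)
  dEle <- potentialEffects(classmap, elevation, elevation, waterBuffer, spec,
                           windows)
  # identical placement/filters => identical retained windows; join on center
  key <- function(d) paste(d$lat, d$lon)
  common <- Reduce(intersect, list(key(dCloud), key(dTree), key(dEle)))
  dCloud <- dCloud[match(common, key(dCloud)), ]
  dTree <- dTree[match(common, key(dTree)), ]
  dEle <- dEle[match(common, key(dEle)), ]

  cloudV <- cloud@values; treeV <- tree@values; elevV <- elevation@values
  buf <- if (is.null(waterBuffer)) matrix(FALSE, nrow(cloudV), ncol(cloudV)) else waterBuffer
  sz <- spec$size
  wkey <- paste(windows$lat, windows$lon)
  sens <- lapply(match(common, wkey), function(k) {
    rows <- windows$row0[k]:(windows$row0[k] + sz - 1L)
    cols <- windows$col0[k]:(windows$col0[k] + sz - 1L)
    keep <- !buf[rows, cols] &
      classmap@classes[rows, cols] != CLASS_CODES[["MASKED"]]
    fitWindowSensitivities(cloudV[rows, cols][keep], treeV[rows, cols][keep],
                           elevV[rows, cols][keep])
  })
  okFit <- vapply(sens, function(s) is.null(s$reason), logical(1))
  rejected <- table(unlist(lapply(sens[!okFit], `[[`, "reason")))
  wtab <- data.frame(lat = dCloud$lat, lon = dCloud$lon,
                     delta = dCloud$delta, dTree = dTree$delta,
                     dEle = dEle$delta,
                     sTree = vapply(sens, function(s) s$sTree %||% NA_real_, 0),
                     sEle = vapply(sens, function(s) s$sEle %||% NA_real_, 0))
  wtab <- wtab[okFit, , drop = FALSE]

  cellMean <- function(col) {
    em <- aggregateToDisplay(wtab, displayRes, deltaColumn = col)
    em@delta@values
  }
  em0 <- aggregateToDisplay(wtab, displayRes)
  dm <- em0@delta
  cells <- data.frame(
    lat = rep(dm@lat, times = ncol(dm@values))[!is.na(dm@values)],
    lon = rep(dm@lon, each = nrow(dm@values))[!is.na(dm@values)])
  ok <- !is.na(dm@values)
  cells$delta <- dm@values[ok]
  cells$dTree <- cellMean("dTree")[ok]
  cells$dEle <- cellMean("dEle")[ok]
  cells$sTree <- cellMean("sTree")[ok]
  cells$sEle <- cellMean("sEle")[ok]
  dec <- decomposeEffect(cells$sTree, cells$sEle, cells$dTree, cells$dEle)
  cells$dCloudTree <- dec$dCloudTree
  cells$dCloudEle <- dec$dCloudEle
  cells$class <- classifyAttribution(cells$delta, cells$dCloudTree,
                                     cells$dCloudEle)
  shares <- 100 * table(factor(cells$class, levels = ATTRIBUTION_CODES,
                               labels = names(ATTRIBUTION_CODES))) /
    sum(!is.na(cells$class))
  list(windows = wtab, cells = cells,
       explained = if (nrow(cells) >= 3)
         reconstructionExplained(cells$delta,
                                 cells$dCloudTree + cells$dCloudEle) else NA_real_,
       classShares = shares, rejectedFits = rejected)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
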