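#' Construct a GridField
#'
#' @param values numeric matrix (rows = latitude south to north, columns =
#'   longitude west to east); `NA` marks nodata.
#' @param resolution degrees per cell.
#' @param originLat,originLon degrees of the south-west corner (cell edge);
#'   cell centers are offset half a cell inward. Ignored when `lat`/`lon`
#'   are supplied.
#' @param lat,lon optional explicit cell-center axes.
#' @param variable,units variable name and units tag.
#' @param fraction declare the field fraction-valued (enforces \[0,1\]).
#' @return a [GridField-class].
#' @examples
#' f <- gridField(matrix(runif(16), 4), resolution = 0.05)
#' @export
gridField <- function(values, resolution, originLat = 0, originLon = 0,
                      lat = NULL, lon = NULL, variable = "field",
                      units = "1", fraction = FALSE) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(lat)) lat <- originLat + (seq_len(nrow(values)) - 0.5) * resolution
  if (is.null(lon)) lon <- originLon + (seq_len(ncol(values)) - 0.5) * resolution
  new("GridField", values = values, lat = as.numeric(lat), lon = as.numeric(lon),
      resolution = resolution, variable = variable, units = units,
      fraction = fraction)
}

#' Construct a GridStack from slice matrices
#'
#' @param slices list of matrices, or a 3-D array `[lat, lon, time]`.
#' @param time numeric time labels (year, month 1-12, or hour 0-23), one per
#'   slice; slices are reordered so labels are sorted.
#' @param timeUnit `"year"`, `"month"` or `"hour"`.
#' @inheritParams gridField
#' @return a [GridStack-class].
#' @export
gridStack <- function(slices, time, timeUnit = "year", resolution,
                      originLat = 0, originLon = 0, lat = NULL, lon = NULL,
                      variable = "field", units = "1", fraction = FALSE) {
  if (is.list(slices)) {
    d <- dim(slices[[1]])
    arr <- array(NA_real_, c(d, length(slices)))
    for (k in seq_along(slices)) arr[, , k] <- slices[[k]]
  } else arr <- slices
  o <- order(time)
  arr <- arr[, , o, drop = FALSE]
  time <- time[o]
  if (is.null(lat)) lat <- originLat + (seq_len(dim(arr)[1]) - 0.5) * resolution
  if (is.null(lon)) lon <- originLon + (seq_len(dim(arr)[2]) - 0.5) * resolution
  new("GridStack", values = arr, lat = as.numeric(lat), lon = as.numeric(lon),
      resolution = resolution, variable = variable, units = units,
      fraction = fraction, time = as.numeric(time), timeUnit = timeUnit)
}

#' Accessors for raster objects
#'
#' `gridValues` returns the value matrix/array, `latAxis`/`lonAxis` the
#' cell-center coordinate vectors, `resolutionDeg` the cell size in degrees,
#' `variableName` the variable tag and `timeAxis` the time labels of a stack.
#'
#' @param x a [GridField-class], [GridStack-class] or [SurfaceClassMap-class].
#' @name gridValues
#' @aliases latAxis lonAxis resolutionDeg variableName timeAxis
NULL

setMethod("gridValues", "GridField", function(x) x@values)
setMethod("gridValues", "GridStack", function(x) x@values)
setMethod("gridValues", "SurfaceClassMap", function(x) x@classes)
for (cl in c("GridField", "GridStack", "SurfaceClassMap")) {
  setMethod("latAxis", cl, function(x) x@lat)
  setMethod("lonAxis", cl, function(x) x@lon)
  setMethod("resolutionDeg", cl, function(x) x@resolution)
}
setMethod("variableName", "GridField", function(x) x@variable)
setMethod("variableName", "GridStack", function(x) x@variable)
setMethod("timeAxis", "GridStack", function(x) x@time)

setMethod("show", "GridField", function(object) {
  v <- object@values
  cat(sprintf("GridField \"%s\" [%s]: %d x %d @ %g deg, lat [%g, %g], lon [%g, %g], %d nodata\n",
              object@variable, object@units, nrow(v), ncol(v),
              object@resolution, min(object@lat), max(object@lat),
              min(object@lon), max(object@lon), sum(is.na(v))))
})

setMethod("show", "GridStack", function(object) {
  d <- dim(object@values)
  cat(sprintf("GridStack \"%s\" [%s]: %d x %d x %d (%s %s..%s) @ %g deg\n",
              object@variable, object@units, d[1], d[2], d[3],
              object@timeUnit, format(min(object@time)), format(max(object@time)),
              object@resolution))
})

setMethod("show", "SurfaceClassMap", function(object) {
  tab <- table(factor(object@classes, levels = CLASS_CODES,
                      labels = names(CLASS_CODES)))
  cat(sprintf("SurfaceClassMap %d x %d @ %g deg\n", nrow(object@classes),
              ncol(object@classes), object@resolution))
  print(tab)
})

.same_geometry <- function(a, b, tol = 1e-9) {
  length(a@lat) == length(b@lat) && length(a@lon) == length(b@lon) &&
    all(abs(a@lat - b@lat) <= tol) && all(abs(a@lon - b@lon) <= tol)
}

.stop_geometry <- function(a, b, what) {
  if (!.same_geometry(a, b))
    stop(sprintf("geometry mismatch: %s", what), call. = FALSE)
}

#' Extract one slice of a stack as a GridField
#'
#' @param stack a [GridStack-class].
#' @param label a time label present in `timeAxis(stack)`.
#' @export
getSlice <- function(stack, label) {
  k <- match(label, stack@time)
  if (is.na(k)) stop("time label not present in stack", call. = FALSE)
  gridField(stack@values[, , k], stack@resolution, lat = stack@lat,
            lon = stack@lon, variable = stack@variable, units = stack@units,
            fraction = stack@fraction)
}

#' Temporal mean of a stack
#'
#' Per-cell mean over (a subset of) time labels, ignoring nodata; a cell is
#' nodata only when all selected slices are nodata. Used to form the
#' multiyear mean fields that the window estimator differences.
#'
#' @param stack a [GridStack-class].
#' @param labels time labels to average over (default: all).
#' @return a [GridField-class].
#' @export
stackMean <- function(stack, labels = NULL) {
  keep <- if (is.null(labels)) seq_along(stack@time) else match(labels, stack@time)
  if (anyNA(keep)) stop("unknown time label", call. = FALSE)
  sub <- stack@values[, , keep, drop = FALSE]
  m <- apply(sub, c(1, 2), function(z) if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE))
  gridField(m, stack@resolution, lat = stack@lat, lon = stack@lon,
            variable = stack@variable, units = stack@units,
            fraction = stack@fraction)
}

.block_index <- function(n, factor) rep(seq_len(n %/% factor), each = factor)

.block_mean <- function(v, factor) {
  n <- nrow(v); p <- ncol(v)
  if (n %% factor != 0L || p %% factor != 0L)
    stop(sprintf("aggregation factor %d does not divide grid dimensions %d x %d",
                 factor, n, p), call. = FALSE)
  ir <- .block_index(n, factor); ic <- .block_index(p, factor)
  ok <- !is.na(v)
  vv <- v; vv[!ok] <- 0
  sums <- t(rowsum(t(rowsum(vv, ir)), ic))
  cnts <- t(rowsum(t(rowsum(ok + 0, ir)), ic))
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  dimnames(out) <- NULL
  out
}

.block_major <- function(v, factor) {
  n <- nrow(v); p <- ncol(v)
  if (n %% factor != 0L || p %% factor != 0L)
    stop(sprintf("aggregation factor %d does not divide grid dimensions %d x %d",
                 factor, n, p), call. = FALSE)
  nb <- n %/% factor; pb <- p %/% factor
  out <- matrix(NA_real_, nb, pb)
  for (i in seq_len(nb)) for (j in seq_len(pb)) {
    blk <- v[((i - 1) * factor + 1):(i * factor),
             ((j - 1) * factor + 1):(j * factor)]
    blk <- as.integer(blk[!is.na(blk)])
    if (length(blk)) {
      shift <- min(blk) - 1L          # support arbitrary (incl. 0) codes
      tab <- tabulate(blk - shift)
      out[i, j] <- which.max(tab) + shift  # first max = smallest code
    }
  }
  out
}

.coarse_axis <- function(ax, factor) colMeans(matrix(ax, nrow = factor))

#' Block-mean aggregation to a coarser grid
#'
#' Each coarse cell is the mean of its `factor` x `factor` fine cells,
#' ignoring nodata; a coarse cell is nodata only when every constituent is.
#' The factor must divide both grid dimensions.
#'
#' @param x a [GridField-class] or [GridStack-class].
#' @param factor positive integer aggregation factor.
#' @return object of the same class at `factor` times coarser resolution.
#' @rdname aggregateMean
#' @export
setMethod("aggregateMean", "GridField", function(x, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  gridField(.block_mean(x@values, factor), x@resolution * factor,
            lat = .coarse_axis(x@lat, factor), lon = .coarse_axis(x@lon, factor),
            variable = x@variable, units = x@units, fraction = x@fraction)
})

#' @rdname aggregateMean
#' @export
setMethod("aggregateMean", "GridStack", function(x, factor) {
  factor <- as.integer(factor)
  slices <- lapply(seq_along(x@time), function(k) .block_mean(x@values[, , k], factor))
  gridStack(slices, x@time, x@timeUnit, x@resolution * factor,
            lat = .coarse_axis(x@lat, factor), lon = .coarse_axis(x@lon, factor),
            variable = x@variable, units = x@units, fraction = x@fraction)
})

#' Majority (modal) aggregation for categorical fields
#'
#' Each coarse cell takes the modal category among its unmasked fine cells;
#' ties break to the smallest category code, all-nodata blocks stay nodata.
#'
#' @inheritParams aggregateMean
#' @rdname aggregateMajor
#' @export
setMethod("aggregateMajor", "GridField", function(x, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  gridField(.block_major(x@values, factor), x@resolution * factor,
            lat = .coarse_axis(x@lat, factor), lon = .coarse_axis(x@lon, factor),
            variable = x@variable, units = x@units, fraction = FALSE)
})
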