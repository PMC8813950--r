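#' Raster I/O: ESRI ASCII grid files and stack directories
#'
#' Single 2-D fields are stored as ESRI ASCII grids (`.asc`), a plain-text
#' raster interchange format with explicit nodata metadata, plus a small
#' JSON sidecar (`<path>.json`) carrying the variable name, units and the
#' fraction-valued flag. Values are written at 17 significant digits so a
#' write/read round trip preserves doubles bit-exactly. Stacks are stored
#' as a directory of one `.asc` per slice plus a `manifest.json` with the
#' time labels; all members must share one geometry.
#'
#' @param field a [GridField-class].
#' @param path file path (`.asc` extension recommended).
#' @param nodata sentinel written for nodata cells.
#' @return `writeAsciiGrid` returns `path` invisibly; `readAsciiGrid`
#'   returns a [GridField-class].
#' @name raster-io
NULL

#' @rdname raster-io
#' @export
writeAsciiGrid <- function(field, path, nodata = -9999) {
  v <- field@values
  res <- field@resolution
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(v)),
               sprintf("nrows %d", nrow(v)),
               sprintf("xllcorner %.17g", field@lon[1] - res / 2),
               sprintf("yllcorner %.17g", field@lat[1] - res / 2),
               sprintf("cellsize %.17g", res),
               sprintf("NODATA_value %.17g", nodata)), con)
  for (i in rev(seq_len(nrow(v)))) {   # rows north to south
    row <- v[i, ]
    row[is.na(row)] <- nodata
    writeLines(paste(sprintf("%.17g", row), collapse = " "), con)
  }
  meta <- list(variable = field@variable, units = field@units,
               fraction = field@fraction)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname raster-io
#' @export
readAsciiGrid <- function(path) {
  hdr <- list()
  con <- file(path, "r")
  on.exit(close(con))
  for (k in 1:6) {
    parts <- strsplit(trimws(readLines(con, 1L)), "[[:space:]]+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  vals <- scan(con, what = double(), n = nc * nr, quiet = TRUE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE]   # back to south-first rows
  m[m == hdr$nodata_value] <- NA_real_
  meta <- list(variable = "field", units = "1", fraction = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- utils::modifyList(meta, jsonlite::read_json(sidecar))
  gridField(m, hdr$cellsize, originLat = hdr$yllcorner, originLon = hdr$xllcorner,
            variable = meta$variable, units = meta$units,
            fraction = isTRUE(meta$fraction))
}

#' @rdname raster-io
#' @param stack a [GridStack-class].
#' @param dir directory for the stack (created if needed).
#' @export
writeGridStack <- function(stack, dir, nodata = -9999) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("slice_%03d.asc", seq_along(stack@time))
  for (k in seq_along(stack@time))
    writeAsciiGrid(getSlice(stack, stack@time[k]), file.path(dir, files[k]),
                   nodata = nodata)
  jsonlite::write_json(
    list(variable = stack@variable, units = stack@units,
         fraction = stack@fraction, timeUnit = stack@timeUnit,
         time = stack@time, files = files),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname raster-io
#' @export
readGridStack <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  fields <- lapply(man$files, function(f) readAsciiGrid(file.path(dir, f)))
  ref <- fields[[1]]
  for (f in fields[-1])
    if (!.same_geometry(ref, f))
      stop("stack members disagree in geometry", call. = FALSE)
  gridStack(lapply(fields, slot, "values"), as.numeric(man$time),
            man$timeUnit, ref@resolution, lat = ref@lat, lon = ref@lon,
            variable = man$variable, units = man$units,
            fraction = isTRUE(man$fraction))
}

#' Serialize a surface-class map
#'
#' Written as a single-band categorical ASCII grid whose integer codes are
#' documented in the JSON sidecar (the [CLASS_CODES] table).
#'
#' @param classmap a [SurfaceClassMap-class].
#' @param path output `.asc` path.
#' @export
writeClassMap <- function(classmap, path) {
  f <- gridField(classmap@classes + 0.0, classmap@resolution,
                 lat = classmap@lat, lon = classmap@lon,
                 variable = "surface_class", units = "code")
  writeAsciiGrid(f, path)
  jsonlite::write_json(list(variable = "surface_class", units = "code",
                            fraction = FALSE, codes = as.list(CLASS_CODES)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Serialize a synthetic scene to a directory
#'
#' One `.asc` (or stack subdirectory) per member plus a plain-text YAML
#' manifest of the generative ground-truth parameters.
#'
#' @param scene a [SyntheticScene-class].
#' @param dir output directory.
#' @export
writeScene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeAsciiGrid(scene@elevation, file.path(dir, "elevation.asc"))
  writeAsciiGrid(scene@tree2000, file.path(dir, "tree2000.asc"))
  writeAsciiGrid(scene@gain, file.path(dir, "gain.asc"))
  writeAsciiGrid(scene@landcover, file.path(dir, "landcover.asc"))
  writeAsciiGrid(scene@waterMask, file.path(dir, "water_mask.asc"))
  writeAsciiGrid(scene@sTreeMap, file.path(dir, "s_tree_true.asc"))
  writeGridStack(scene@yearlyLoss, file.path(dir, "yearly_loss"))
  writeGridStack(scene@cloudYearly, file.path(dir, "cloud_yearly"))
  writeGridStack(scene@cloudMonthly, file.path(dir, "cloud_monthly"))
  if (is(scene@cloudHourly, "GridStack"))
    writeGridStack(scene@cloudHourly, file.path(dir, "cloud_hourly"))
  if (length(scene@typeFractions))
    for (k in seq_along(scene@typeFractions))
      writeAsciiGrid(scene@typeFractions[[k]],
                     file.path(dir, sprintf("cloud_type_%d.asc", k)))
  utils::write.csv(scene@conversionTable, file.path(dir, "conversion_table.csv"),
                   row.names = FALSE)
  yaml::write_yaml(configAsList(scene@config), file.path(dir, "scene_config.yaml"))
  invisible(dir)
}
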