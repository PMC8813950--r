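.log_levels <- c(debug = 1L, info = 2L, warn = 3L)

.make_logger <- function(outdir, logLevel = "info") {
  logFile <- file.path(outdir, "run.log")
  threshold <- .log_levels[[logLevel]]
  function(level, fmt, ...) {
    msg <- sprintf(fmt, ...)
    line <- sprintf("[%s] %s", toupper(level), msg)
    cat(line, "\n", file = logFile, append = TRUE, sep = "")
    if (.log_levels[[level]] >= threshold) message(line)
  }
}

.pipeline_stages <- c("simulate", "classify", "effects", "attribute",
                      "cloudtypes", "trends", "scale", "heatlink", "report")

#' Run the analysis pipeline
#'
#' Orchestrates the stages `simulate -> classify -> effects -> attribute ->
#' cloudtypes -> trends -> scale -> heatlink -> report` on a synthetic
#' scene described by a declarative config (a YAML file path or a nested
#' list). Each stage writes its tabular outputs (CSV) and maps (ASCII
#' grids) under `outdir` and logs placement/rejection counts to stderr and
#' `run.log`; re-running with the same config and seed reproduces
#' byte-identical tabular outputs.
#'
#' Config keys (all optional): `scene` ([sceneConfig()] arguments),
#' `window` ([windowSpec()] arguments), `classifier` ([classifierConfig()]
#' arguments), `displayRes`, `lossFractionMin`, `region`, `scale`
#' (logical).
#'
#' @param config YAML file path or nested list.
#' @param stages character subset of the stage names, in pipeline order.
#' @param outdir output directory (created).
#' @param seed integer; overrides the scene seed for end-to-end
#'   determinism.
#' @param logLevel `"debug"`, `"info"` or `"warn"`.
#' @return invisibly, a list of in-memory stage artifacts.
#' @export
runPipeline <- function(config = list(), stages = setdiff(.pipeline_stages, "scale"),
                        outdir, seed = NULL, logLevel = "info") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(all(stages %in% .pipeline_stages))
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- .make_logger(outdir, logLevel)
  art <- new.env(parent = emptyenv())
  need <- function(what, stage) {
    if (!exists(what, art))
      stop(sprintf("stage '%s' requires artifact '%s' from an earlier stage",
                   stage, what), call. = FALSE)
    get(what, art)
  }
  sceneArgs <- config$scene %||% list()
  if (!is.null(seed)) sceneArgs$seed <- seed
  if (is.null(sceneArgs$withTypes)) sceneArgs$withTypes <- TRUE
  spec <- do.call(windowSpec, config$window %||% list())
  classifier <- do.call(classifierConfig, config$classifier %||% list())
  displayRes <- config$displayRes %||% 0.5
  lossFractionMin <- config$lossFractionMin %||% 0.05

  for (stage in stages) {
    log("info", "stage %s", stage)
    switch(stage,
      simulate = {
        scene <- generateScene(do.call(sceneConfig, sceneArgs))
        writeScene(scene, file.path(outdir, "scene"))
        assign("scene", scene, art)
        log("info", "scene %d x %d, %d years", scene@config@nLat,
            scene@config@nLon, length(scene@config@years))
      },
      classify = {
        scene <- need("scene", stage)
        cm <- classifyScene(scene, classifier)
        writeClassMap(cm, file.path(outdir, "classmap.asc"))
        assign("classmap", cm, art)
        assign("waterBuffer", bufferWaterMask(scene@waterMask), art)
        tab <- table(factor(cm@classes, levels = CLASS_CODES,
                            labels = names(CLASS_CODES)))
        log("info", "classes: %s", paste(names(tab), tab, collapse = ", "))
      },
      effects = {
        scene <- need("scene", stage); cm <- need("classmap", stage)
        cloudMean <- stackMean(scene@cloudYearly)
        windows <- placeWindows(cm, spec)
        sam <- potentialEffects(cm, cloudMean, scene@elevation,
                                get("waterBuffer", art), spec, windows)
        act <- actualEffects(cm, cloudMean, scene@elevation,
                             get("waterBuffer", art), spec, windows)
        cnt <- attr(sam, "counts")
        log("info", "windows placed %d, retained %d, rejected %d",
            cnt[["placed"]], cnt[["retained"]],
            cnt[["placed"]] - cnt[["retained"]])
        utils::write.csv(sam, file.path(outdir, "potential_samples.csv"),
                         row.names = FALSE)
        utils::write.csv(act, file.path(outdir, "actual_samples.csv"),
                         row.names = FALSE)
        em <- aggregateToDisplay(sam, displayRes)
        writeAsciiGrid(em@delta, file.path(outdir, "effect_map.asc"))
        assign("cloudMean", cloudMean, art)
        assign("windows", windows, art)
        assign("potential", sam, art); assign("actual", act, art)
        assign("effectMap", em, art)
        sf <- signFractions(em)
        log("info", "enhancement %.1f%%, inhibition %.1f%%",
            sf[["positive"]], sf[["negative"]])
      },
      attribute = {
        scene <- need("scene", stage); cm <- need("classmap", stage)
        att <- attributeEffects(cm, need("cloudMean", stage),
                                treeMeanField(scene), scene@elevation,
                                get("waterBuffer", art), spec, displayRes)
        utils::write.csv(att$cells, file.path(outdir, "attribution_cells.csv"),
                         row.names = FALSE)
        assign("attribution", att, art)
        log("info", "attribution explained R2 = %.3f", att$explained)
      },
      cloudtypes = {
        scene <- need("scene", stage); cm <- need("classmap", stage)
        if (!length(scene@typeFractions))
          stop("stage 'cloudtypes' requires a scene generated with withTypes",
               call. = FALSE)
        pte <- perTypeEffects(cm, scene@typeFractions,
                              stackMean(scene@cloudYearly), scene@elevation,
                              get("waterBuffer", art), spec, displayRes)
        utils::write.csv(pte$cells, file.path(outdir, "cloudtype_cells.csv"),
                         row.names = FALSE)
        assign("cloudtypes", pte, art)
        cdf <- convectiveDominanceFraction(pte$cells$dominant)
        log("info", "convective dominance %.1f%% (shallow %.1f%%)",
            cdf[["convective"]], cdf[["shallow"]])
      },
      trends = {
        scene <- need("scene", stage); cm <- need("classmap", stage)
        ser <- annualEffectSeries(scene@cloudYearly, cm, scene@yearlyLoss,
                                  region = config$region,
                                  lossFractionMin = lossFractionMin,
                                  elevation = scene@elevation,
                                  waterBuffer = get("waterBuffer", art),
                                  spec = spec, displayRes = displayRes)
        tr <- fitTrend(ser)
        dts <- deltaTreeSeries(cm, scene@tree2000, scene@yearlyLoss,
                               years = timeAxis(scene@cloudYearly))
        utils::write.csv(merge(ser, dts), file.path(outdir, "annual_series.csv"),
                         row.names = FALSE)
        assign("annualSeries", ser, art); assign("trend", tr, art)
        log("info", "trend %.4f %%/yr, total %.3f%%, p %.3g",
            tr$slope, tr$totalChange, tr$pValue)
      },
      scale = {
        scene <- need("scene", stage)
        tab <- rescaleExperiment(scene, classifier = classifier)
        utils::write.csv(tab, file.path(outdir, "scale_experiment.csv"),
                         row.names = FALSE)
        assign("scaleTable", tab, art)
      },
      heatlink = {
        scene <- need("scene", stage); cm <- need("classmap", stage)
        hs <- heatLinkSamples(cm, scene@landcover, need("cloudMean", stage),
                              scene@conversionTable, scene@elevation,
                              get("waterBuffer", art), spec)
        utils::write.csv(hs, file.path(outdir, "heatlink_samples.csv"),
                         row.names = FALSE)
        assign("heatlink", hs, art)
        if (nrow(hs) >= 4) {
          rc <- rankCorrelation(hs$deltaH, hs$delta)
          assign("heatlinkRho", rc, art)
          log("info", "deltaH-deltaCloud Spearman rho %.3f (p %.3g, n %d)",
              rc$rho, rc$pValue, rc$n)
        }
      },
      report = {
        lines <- c("forestcloud pipeline report", "")
        if (exists("potential", art)) {
          sf <- signFractions(get("effectMap", art))
          cnt <- attr(get("potential", art), "counts")
          lines <- c(lines,
            sprintf("windows: placed %d, retained %d (elevation s.d. %d, low counts %d)",
                    cnt[["placed"]], cnt[["retained"]],
                    cnt[["elevation_sd"]],
                    cnt[["min_count_a"]] + cnt[["min_count_b"]]),
            sprintf("potential effect: mean %+.5f; enhancement %.2f%%, inhibition %.2f%%",
                    mean(get("potential", art)$delta), sf[["positive"]],
                    sf[["negative"]]),
            sprintf("actual effect (loss vs forest): mean %+.5f",
                    mean(get("actual", art)$delta)))
        }
        if (exists("attribution", art)) {
          sh <- get("attribution", art)$classShares
          lines <- c(lines, sprintf("attribution: %s; explained R2 %.3f",
                                    paste(names(sh), sprintf("%.1f%%", sh),
                                          collapse = ", "),
                                    get("attribution", art)$explained))
        }
        if (exists("cloudtypes", art)) {
          cdf <- convectiveDominanceFraction(get("cloudtypes", art)$cells$dominant)
          lines <- c(lines, sprintf("convective dominance: %.2f%% (shallow %.2f%%)",
                                    cdf[["convective"]], cdf[["shallow"]]))
        }
        if (exists("trend", art)) {
          tr <- get("trend", art)
          lines <- c(lines, sprintf("hotspot trend: %+.4f %%/yr over %d years, total %+.3f%%, p %.3g",
                                    tr$slope, tr$nYears, tr$totalChange,
                                    tr$pValue))
        }
        if (exists("heatlinkRho", art)) {
          rc <- get("heatlinkRho", art)
          lines <- c(lines, sprintf("heat link: Spearman rho %.3f, p %.3g, n %d",
                                    rc$rho, rc$pValue, rc$n))
        }
        writeLines(lines, file.path(outdir, "report.txt"))
        log("info", "report written")
      })
  }
  invisible(as.list(art))
}

#' Multiyear mean tree-cover field of a scene
#'
#' Baseline tree cover minus the per-year mean of accumulated loss (plus
#' gain), the tree-cover analogue of the multiyear mean cloud field.
#'
#' @param scene a [SyntheticScene-class].
#' @return a [GridField-class].
#' @export
treeMeanField <- function(scene) {
  lossYears <- scene@yearlyLoss@time
  years <- scene@cloudYearly@time
  cum <- 0
  acc <- matrix(0, length(scene@tree2000@lat), length(scene@tree2000@lon))
  for (y in years) {
    keep <- which(lossYears <= y)
    cumLoss <- if (length(keep))
      apply(scene@yearlyLoss@values[, , keep, drop = FALSE], c(1, 2), sum)
    else acc * 0
    acc <- acc + cumLoss
  }
  v <- pmax(scene@tree2000@values - acc / length(years) +
              scene@gain@values, 0)
  gridField(v, scene@tree2000@resolution, lat = scene@tree2000@lat,
            lon = scene@tree2000@lon, variable = "tree_cover_mean",
            fraction = TRUE)
}
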