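#' ISCCP cloud-type scheme
#'
#' The standard 3 x 3 classification by cloud-top pressure (high / mid /
#' low altitude at 440 and 680 hPa) and cloud optical depth (thin /
#' medium / thick at 3.6 and 23): 1 cirrus, 2 cirrostratus, 3 deep
#' convection (high); 4 altocumulus, 5 altostratus, 6 nimbostratus (mid);
#' 7 cumulus, 8 stratocumulus, 9 stratus (low). Types 3, 7, 8 are
#' convective; 7 and 8 are the shallow convective subset.
#'
#' @param ctpBounds increasing hPa boundaries (default 440, 680).
#' @param tauBounds increasing optical-depth boundaries (default 3.6, 23).
#' @return list of class `CloudTypeScheme` with the code table, type names
#'   and the convective sets.
#' @export
cloudTypeScheme <- function(ctpBounds = c(440, 680), tauBounds = c(3.6, 23)) {
  stopifnot(length(ctpBounds) == 2L, diff(ctpBounds) > 0,
            length(tauBounds) == 2L, diff(tauBounds) > 0)
  codes <- matrix(1:9, nrow = 3, byrow = TRUE)  # [ctp bin, tau bin]
  structure(list(ctpBounds = ctpBounds, tauBounds = tauBounds,
                 codeTable = codes,
                 typeNames = c("cirrus", "cirrostratus", "deep_convection",
                               "altocumulus", "altostratus", "nimbostratus",
                               "cumulus", "stratocumulus", "stratus"),
                 convective = c(3L, 7L, 8L), shallowConvective = c(7L, 8L)),
            class = "CloudTypeScheme")
}

#' Classify observations into the nine ISCCP types
#'
#' Boundary values assign to the higher-altitude (lower pressure) and
#' thinner (lower tau) bin. `NA` in either input propagates.
#'
#' @param ctp cloud-top pressure in hPa (> 0), vectorized.
#' @param tau cloud optical depth (>= 0), vectorized.
#' @param scheme a [cloudTypeScheme()].
#' @return integer type codes 1-9.
#' @export
classifyIsccp <- function(ctp, tau, scheme = cloudTypeScheme()) {
  ok <- !(is.na(ctp) | is.na(tau))
  if (any(ctp[ok] <= 0)) stop("cloud-top pressure must be positive")
  if (any(tau[ok] < 0)) stop("optical depth must be non-negative")
  ctpBin <- 1L + (ctp > scheme$ctpBounds[1]) + (ctp > scheme$ctpBounds[2])
  tauBin <- 1L + (tau > scheme$tauBounds[1]) + (tau > scheme$tauBounds[2])
  out <- scheme$codeTable[cbind(ctpBin, tauBin)]
  out[!ok] <- NA_integer_
  as.integer(out)
}

#' Per-type window effects with the sum identity
#'
#' Applies the window estimator to the total cloud fraction and to each of
#' the nine per-type fractional-cover fields (which must sum per pixel to
#' the total within 1e-6), aggregates to the display grid and determines
#' the dominant type per cell. Because the class means are linear, the
#' per-type effects sum to the total effect exactly.
#'
#' @param classmap a [SurfaceClassMap-class].
#' @param typeFields list of nine per-type [GridField-class]s.
#' @param totalCloud total cloud fraction [GridField-class].
#' @param elevation,waterBuffer,spec,displayRes as in [potentialEffects()].
#' @param scheme a [cloudTypeScheme()].
#' @return list with `cells` (per display cell: `delta1`..`delta9`,
#'   `total`, `dominant`) and `windows` (per-window per-type deltas).
#' @export
perTypeEffects <- function(classmap, typeFields, totalCloud,
                           elevation = NULL, waterBuffer = NULL,
                           spec = windowSpec(), displayRes = 0.5,
                           scheme = cloudTypeScheme()) {
  stopifnot(length(typeFields) == 9L)
  sumV <- Reduce(`+`, lapply(typeFields, slot, "values"))
  mismatch <- abs(sumV - totalCloud@values)
  if (any(mismatch > 1e-6, na.rm = TRUE))
    stop("per-type cloud fractions do not sum to the total cloud fraction",
         call. = FALSE)
  windows <- placeWindows(classmap, spec)
  tot <- potentialEffects(classmap, totalCloud, elevation, waterBuffer,
                          spec, windows)
  perType <- lapply(typeFields, function(f)
    potentialEffects(classmap, f, elevation, waterBuffer, spec, windows))
  wtab <- tot[c("lat", "lon")]
  wtab$total <- tot$delta
  for (t in 1:9) wtab[[paste0("delta", t)]] <- perType[[t]]$delta

  em <- aggregateToDisplay(wtab, displayRes, deltaColumn = "total")
  ok <- !is.na(em@delta@values)
  cells <- data.frame(
    lat = rep(em@delta@lat, times = ncol(em@delta@values))[ok],
    lon = rep(em@delta@lon, each = nrow(em@delta@values))[ok],
    total = em@delta@values[ok])
  for (t in 1:9)
    cells[[paste0("delta", t)]] <-
      aggregateToDisplay(wtab, displayRes,
                         deltaColumn = paste0("delta", t))@delta@values[ok]
  deltaMat <- as.matrix(cells[paste0("delta", 1:9)])
  cells$dominant <- vapply(seq_len(nrow(cells)), function(i)
    dominantType(deltaMat[i, ], cells$total[i]), integer(1))
  list(cells = cells, windows = wtab)
}

#' Dominant cloud type of a per-type effect record
#'
#' Among types whose effect shares the sign of the total effect, the one
#' with the largest magnitude; ties break to the smallest code; `NA` when
#' no type shares the sign (or the total is zero).
#'
#' @param typeDeltas numeric length-9 per-type effects.
#' @param total total effect.
#' @return integer code 1-9 or `NA`.
#' @export
dominantType <- function(typeDeltas, total) {
  stopifnot(length(typeDeltas) == 9L)
  if (is.na(total) || total == 0) return(NA_integer_)
  cand <- which(!is.na(typeDeltas) & sign(typeDeltas) == sign(total))
  if (!length(cand)) return(NA_integer_)
  as.integer(cand[which.max(abs(typeDeltas[cand]))])
}

#' Convective dominance share
#'
#' Percent of valid cells whose dominant type is convective (deep
#' convection, cumulus, stratocumulus) and the shallow-convective share
#' (cumulus, stratocumulus) alongside.
#'
#' @param dominant integer vector (or matrix) of dominant type codes.
#' @param scheme a [cloudTypeScheme()].
#' @return named numeric `c(convective = , shallow = )` in percent.
#' @export
convectiveDominanceFraction <- function(dominant, scheme = cloudTypeScheme()) {
  d <- dominant[!is.na(dominant)]
  if (!length(d)) return(c(convective = NA_real_, shallow = NA_real_))
  c(convective = 100 * mean(d %in% scheme$convective),
    shallow = 100 * mean(d %in% scheme$shallowConvective))
}
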