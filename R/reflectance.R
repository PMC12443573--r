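# Radiometric calibration against the reference whiteboard, zonal per-plot
# reflectance extraction, and stage-dynamics summaries.

#' Calibrate digital numbers to reflectance
#'
#' Single-point calibration against the reference whiteboard: reflectance =
#' dn x whiteboardRefl / whiteboardDN. The whiteboard reads DN 65000 at
#' 99.8\% reflectivity, so dn = 65000 maps to 0.998. Linear through the
#' origin; no dark-current term.
#'
#' @param dn non-negative digital number(s).
#' @param whiteboardDN whiteboard digital number (default 65000).
#' @param whiteboardRefl whiteboard reflectivity fraction (default 0.998).
#' @return Reflectance fraction(s).
#' @examples
#' dnToReflectance(65000)  # 0.998
#' @export
dnToReflectance <- function(dn, whiteboardDN = 65000,
                            whiteboardRefl = 0.998) {
  if (whiteboardDN <= 0) stopf("whiteboardDN must be > 0")
  if (any(dn < 0, na.rm = TRUE)) stopf("negative DN values are not valid")
  dn * whiteboardRefl / whiteboardDN
}

#' Extract per-plot mean reflectance
#'
#' Zonal statistics over the plot rectangles: for each plot and band, the
#' mean DN over pixels whose centers fall inside the rectangle (inclusive
#' 1-based index ranges in R), calibrated to reflectance. Accepts a
#' \linkS4class{PlotScene} or a raw bundle \code{list(bands = <named list of
#' DN matrices>, plots = <layout data.frame>)}.
#'
#' @param scene a \linkS4class{PlotScene} or raster bundle.
#' @param plots optional layout table overriding the scene's own.
#' @param whiteboardDN,whiteboardRefl calibration constants.
#' @return data.frame with one row per plot: plot, genotype, env, treatment,
#'   stage, r_red, r_rededge, r_nir, r_green, r_blue, n_pixels.
#' @export
extractPlotReflectance <- function(scene, plots = NULL,
                                   whiteboardDN = 65000,
                                   whiteboardRefl = 0.998) {
  if (is(scene, "PlotScene")) {
    bands <- scene@bands
    if (is.null(plots)) plots <- scene@plots
    key <- list(env = scene@env, treatment = scene@treatment,
                stage = scene@stage)
  } else {
    bands <- scene$bands
    if (is.null(plots)) plots <- scene$plots
    key <- list(env = scene$env %||% NA_character_,
                treatment = scene$treatment %||% NA_character_,
                stage = scene$stage %||% NA_character_)
  }
  dm <- dim(bands[[1]])
  if (any(plots$rowMin < 1 | plots$colMin < 1 |
          plots$rowMax > dm[1] | plots$colMax > dm[2]))
    stopf("plot rectangle extends outside the raster extent")
  out <- data.frame(plot = plots$plot, genotype = plots$genotype,
                    env = key$env, treatment = key$treatment,
                    stage = key$stage, stringsAsFactors = FALSE)
  nPix <- (plots$rowMax - plots$rowMin + 1) * (plots$colMax - plots$colMin + 1)
  if (any(nPix <= 0))
    stopf("plot '%s' contains no pixels", plots$plot[which(nPix <= 0)[1]])
  for (b in BAND_NAMES) {
    m <- bands[[b]]
    out[[REFL_COLS[[b]]]] <- vapply(seq_len(nrow(plots)), function(i)
      dnToReflectance(mean(m[plots$rowMin[i]:plots$rowMax[i],
                             plots$colMin[i]:plots$colMax[i]]),
                      whiteboardDN, whiteboardRefl), numeric(1))
  }
  out$n_pixels <- nPix
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Band-by-stage reflectance summary
#'
#' Arithmetic mean reflectance over plots for every (treatment, band, stage)
#' cell, reported in percent, mirroring the standard band-dynamics table.
#'
#' @param plotRefl a plot-reflectance table from
#'   \code{\link{extractPlotReflectance}} (rows from several scenes may be
#'   concatenated).
#' @return data.frame: treatment, band, stage, reflectance_pct.
#' @export
bandStageSummary <- function(plotRefl) {
  if (!nrow(plotRefl)) stopf("empty plot-reflectance table")
  cells <- expand.grid(treatment = unique(plotRefl$treatment),
                       band = BAND_NAMES,
                       stage = intersect(STAGES, unique(plotRefl$stage)),
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    rows <- plotRefl[plotRefl$treatment == cells$treatment[i] &
                     plotRefl$stage == cells$stage[i], ]
    if (!nrow(rows)) {
      warnf("no plots for treatment %s, stage %s; row omitted",
            cells$treatment[i], cells$stage[i])
      return(NULL)
    }
    data.frame(treatment = cells$treatment[i], band = cells$band[i],
               stage = cells$stage[i],
               reflectance_pct = 100 * mean(rows[[REFL_COLS[[cells$band[i]]]]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Percent decrease between two stages
#'
#' 100 x (prev - curr) / prev, rounded to 2 decimals for reporting.
#'
#' @param prev,curr reflectance percentages (prev must be > 0).
#' @return Percent decrease, 2 decimals.
#' @examples
#' percentDecrease(55.14, 37.47)  # 32.05
#' @export
percentDecrease <- function(prev, curr) {
  if (any(prev <= 0)) stopf("prev must be > 0")
  round(100 * (prev - curr) / prev, 2)
}

#' Stage-to-stage percent decreases for a band summary
#'
#' Applies \code{\link{percentDecrease}} to consecutive growth stages
#' (HS to FL and FL to GF) for every treatment and band.
#'
#' @param summary a band-stage summary table (see
#'   \code{\link{bandStageSummary}} or \code{\link{table3Reflectance}}).
#' @return data.frame: treatment, band, from, to, decrease_pct.
#' @export
stageDecreaseTable <- function(summary) {
  out <- list()
  for (tr in unique(summary$treatment)) for (b in unique(summary$band)) {
    rows <- summary[summary$treatment == tr & summary$band == b, ]
    vals <- stats::setNames(rows$reflectance_pct, rows$stage)
    for (i in 1:2) {
      from <- STAGES[i]; to <- STAGES[i + 1]
      if (all(c(from, to) %in% names(vals)))
        out[[length(out) + 1]] <- data.frame(
          treatment = tr, band = b, from = from, to = to,
          decrease_pct = percentDecrease(vals[[from]], vals[[to]]),
          stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
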