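# The 18 vegetation indices computed from five-band reflectance.

# Each entry returns list(num, den) or a direct value; denominators of 0 are
# flagged invalid rather than silently evaluated.
viFormulas <- function(cariMode = c("ratio", "literal")) {
  cariMode <- match.arg(cariMode)
  list(
    NDVI      = function(b) ratioVI(b["Nir"] - b["Red"], b["Nir"] + b["Red"]),
    GNDVI     = function(b) ratioVI(b["Nir"] - b["Green"],
                                    b["Nir"] + b["Green"]),
    NGBDI     = function(b) ratioVI(b["Green"] - b["Blue"],
                                    b["Green"] + b["Blue"]),
    NGRDI     = function(b) ratioVI(b["Green"] - b["Red"],
                                    b["Green"] + b["Red"]),
    RERDVI    = function(b) ratioVI(b["Nir"] - b["RedEdge"],
                                    b["Nir"] + b["RedEdge"]),
    SAVI      = function(b) ratioVI(2.5 * (b["Nir"] - b["Red"]),
                                    b["Nir"] + b["Red"] + 0.5),
    GOSAVI    = function(b) ratioVI(1.16 * (b["Nir"] - b["Green"]),
                                    b["Nir"] + b["Green"] + 0.16),
    REOSAVI   = function(b) ratioVI(1.16 * (b["Nir"] - b["Red"]),
                                    b["Nir"] + b["Red"] + 0.16),
    OSAVI     = function(b) ratioVI(b["Nir"] - b["Red"],
                                    b["Nir"] + b["Red"] + 0.16),
    RVI       = function(b) ratioVI(b["Nir"], b["Red"]),
    DVI       = function(b) okVI(b["Nir"] - b["Red"]),
    GRVI      = function(b) ratioVI(b["Nir"], b["Green"]),
    EXG       = function(b) okVI(2 * b["Green"] - b["Red"] - b["Blue"]),
    TVI       = function(b) okVI(0.5 * (120 * (b["Nir"] - b["Green"]) -
                                        200 * (b["Red"] - b["Green"]))),
    CARI      = function(b) {
      if (cariMode == "ratio")
        ratioVI(b["RedEdge"] - b["Red"], 0.2 * (b["RedEdge"] + b["Red"]))
      else  # literal left-to-right reading: (Re - R) / 0.2 * (Re + R)
        okVI((b["RedEdge"] - b["Red"]) / 0.2 * (b["RedEdge"] + b["Red"]))
    },
    VARIgreen = function(b) ratioVI(b["Green"] - b["Red"],
                                    b["Green"] + b["Red"] - b["Blue"]),
    VARIred   = function(b) ratioVI(b["RedEdge"] - 1.7 * b["Red"] +
                                      0.7 * b["Blue"],
                                    b["RedEdge"] + 2.3 * b["Red"] -
                                      1.3 * b["Blue"]),
    EVI       = function(b) ratioVI(2.5 * (b["Nir"] - b["Red"]),
                                    b["Nir"] + 6 * b["Red"] -
                                      7.5 * b["Blue"] + 1)
  )
}

ratioVI <- function(num, den) {
  if (den == 0) list(value = NA_real_, valid = FALSE)
  else list(value = unname(num / den), valid = TRUE)
}
okVI <- function(value) list(value = unname(value), valid = TRUE)

#' Vegetation index names
#'
#' @return The 18 supported index names.
#' @export
viNames <- function() names(viFormulas())

#' Compute one vegetation index
#'
#' Evaluates the named index exactly per its published formula from five band
#' reflectances. A zero denominator yields \code{NA} with the validity flag
#' attribute set to \code{FALSE}, never a silent zero. The precedence of the
#' printed CARI formula is ambiguous; the default "ratio" reading divides by
#' 0.2 x (RedEdge + Red), the "literal" reading applies the operators left to
#' right.
#'
#' @param name one of \code{\link{viNames}()}.
#' @param bands named numeric vector with entries Red, RedEdge, Nir, Green,
#'   Blue (reflectance fractions).
#' @param cariMode "ratio" (default) or "literal".
#' @return Index value with attribute \code{valid}.
#' @examples
#' computeVI("NDVI", c(Red = 0.0768, RedEdge = 0.3403, Nir = 0.5684,
#'                     Green = 0.1593, Blue = 0.0674))
#' @export
computeVI <- function(name, bands, cariMode = c("ratio", "literal")) {
  forms <- viFormulas(match.arg(cariMode))
  if (!name %in% names(forms))
    stopf("unknown index '%s'; valid names: %s", name,
          paste(names(forms), collapse = ", "))
  if (!all(BAND_NAMES %in% names(bands)))
    stopf("bands must be named %s", paste(BAND_NAMES, collapse = ", "))
  if (!all(is.finite(bands[BAND_NAMES])))
    stopf("band reflectances must be finite")
  res <- forms[[name]](bands)
  structure(res$value, valid = res$valid)
}

#' Compute all 18 vegetation indices per plot
#'
#' Applies every index formula to each row of a plot-reflectance table. A bad
#' denominator flags that single value invalid (\code{NA}) without aborting
#' the batch.
#'
#' @param plotRefl table from \code{\link{extractPlotReflectance}} with the
#'   r_red .. r_blue columns.
#' @param cariMode see \code{\link{computeVI}}.
#' @return data.frame: the key columns of \code{plotRefl} plus 18 index
#'   columns; attribute \code{validity} is a logical matrix of the same
#'   shape flagging computable values.
#' @export
computeAllVI <- function(plotRefl, cariMode = c("ratio", "literal")) {
  if (!nrow(plotRefl)) stopf("empty plot-reflectance table")
  cariMode <- match.arg(cariMode)
  forms <- viFormulas(cariMode)
  keyCols <- intersect(c("plot", "genotype", "env", "treatment", "stage"),
                       names(plotRefl))
  out <- plotRefl[, keyCols, drop = FALSE]
  validity <- matrix(TRUE, nrow(plotRefl), length(forms),
                     dimnames = list(NULL, names(forms)))
  bandMat <- as.matrix(plotRefl[, REFL_COLS])
  colnames(bandMat) <- BAND_NAMES
  for (nm in names(forms)) {
    vals <- numeric(nrow(bandMat))
    for (i in seq_len(nrow(bandMat))) {
      r <- forms[[nm]](bandMat[i, ])
      vals[i] <- r$value
      validity[i, nm] <- r$valid
    }
    out[[nm]] <- vals
  }
  structure(out, validity = validity)
}
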