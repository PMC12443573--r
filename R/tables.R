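# Loaders for the transcription fixtures shipped with the package: the
# published band-stage reflectance means, per-cell locus counts, and the
# measured/predicted overlap locus list. These are the desk-recomputable
# numeric inputs for the summary operations.

fixturePath <- function(name) {
  p <- system.file("extdata", name, package = "spadGWAS")
  if (!nzchar(p)) stopf("fixture '%s' not found in installed package", name)
  p
}

#' Published band-stage reflectance means
#'
#' Mean reflectance (percent) of the five bands per treatment and growth
#' stage, as reported for the emulated trial. Input for
#' \code{\link{stageDecreaseTable}} and the scene renderer's baselines.
#'
#' @return data.frame: treatment, band, stage, reflectance_pct.
#' @export
table3Reflectance <- function() {
  utils::read.csv(fixturePath("band_stage_reflectance.csv"),
                  stringsAsFactors = FALSE)
}

#' Published per-cell locus counts
#'
#' Number of significant loci, minimum P and marker-R2 range per (treatment,
#' source, stage) cell of the reported genome scans.
#'
#' @return data.frame: treatment, source, stage, site_number, p_value,
#'   r2_min_pct, r2_max_pct.
#' @export
table5LocusCounts <- function() {
  utils::read.csv(fixturePath("locus_counts_by_cell.csv"),
                  stringsAsFactors = FALSE)
}

#' Published overlap locus list
#'
#' The 18 measured / 18 predicted representative markers of the overlapping
#' loci, with P-values and marker R2 (percent).
#'
#' @return data.frame: source, marker, chrom, pos, p, marker_r2_pct.
#' @export
table6OverlapLoci <- function() {
  utils::read.csv(fixturePath("overlap_loci.csv"), stringsAsFactors = FALSE)
}
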