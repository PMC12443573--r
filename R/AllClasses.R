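#' @import methods
NULL

#' Simulation configuration
#'
#' Parameters controlling the synthetic wheat trial: the genotype panel, the
#' SNP panel with subpopulation structure, the SPAD forward model, and the
#' five-band scene renderer. Defaults reproduce the design of the emulated
#' study: 119 genotypes in 3 subpopulations, 21 chromosomes, two environments
#' by two water treatments by three growth stages with two replicates.
#'
#' @slot nGenotypes number of genotypes (lines) in the panel.
#' @slot nSnps number of biallelic markers retained after MAF filtering.
#' @slot nChromosomes number of chromosomes (wheat labels 1A..7D).
#' @slot nSubpops number of subpopulations.
#' @slot drift Balding-Nichols drift parameter F (0 = no structure).
#' @slot mafFloor minimum minor-allele frequency retained.
#' @slot nQtl number of planted QTLs.
#' @slot qtlEffectSd standard deviation of planted additive effects, SPAD units.
#' @slot polygenicSd standard deviation of the polygenic genetic term, SPAD units.
#' @slot targetH2 target broad-sense heritability (per stage/treatment cell).
#' @slot bandNoiseSd per-pixel reflectance noise standard deviation (fraction).
#' @slot spadSlope per-band reflectance change per SPAD standard deviation;
#'   negative in the visible bands (more chlorophyll absorbs more light),
#'   positive in the near infrared.
#' @slot plotRows,plotCols plot grid layout of a rendered scene.
#' @slot plotSizePx side length of a square plot, pixels.
#' @slot seed integer seed; fixed seed gives byte-identical outputs.
#' @export
setClass("SimConfig", representation(
  nGenotypes = "numeric", nSnps = "numeric", nChromosomes = "numeric",
  nSubpops = "numeric", drift = "numeric", mafFloor = "numeric",
  nQtl = "numeric", qtlEffectSd = "numeric", polygenicSd = "numeric",
  targetH2 = "numeric", bandNoiseSd = "numeric", spadSlope = "numeric",
  plotRows = "numeric", plotCols = "numeric", plotSizePx = "numeric",
  seed = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  counts <- c(object@nGenotypes, object@nSnps, object@nChromosomes,
              object@nSubpops, object@plotRows, object@plotCols,
              object@plotSizePx)
  if (any(counts < 1)) msg <- c(msg, "all counts must be >= 1")
  if (object@nQtl < 0) msg <- c(msg, "nQtl must be >= 0")
  if (object@targetH2 < 0 || object@targetH2 > 1)
    msg <- c(msg, "targetH2 must lie in [0, 1]")
  if (object@drift < 0 || object@drift >= 1)
    msg <- c(msg, "drift must lie in [0, 1)")
  if (object@mafFloor < 0 || object@mafFloor >= 0.5)
    msg <- c(msg, "mafFloor must lie in [0, 0.5)")
  if (object@bandNoiseSd < 0) msg <- c(msg, "bandNoiseSd must be >= 0")
  if (object@plotRows * object@plotCols < object@nGenotypes)
    msg <- c(msg, "plot grid too small for nGenotypes")
  if (length(object@spadSlope) != 5)
    msg <- c(msg, "spadSlope must have 5 band entries")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' @param nGenotypes,nSnps,nChromosomes,nSubpops,drift,mafFloor,nQtl numbers;
#'   see the class documentation.
#' @param qtlEffectSd,polygenicSd,targetH2,bandNoiseSd,spadSlope,plotRows,plotCols,plotSizePx,seed
#'   numbers; see the class documentation.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nSnps = 500, seed = 1)
#' @export
simConfig <- function(nGenotypes = 119, nSnps = 2000, nChromosomes = 21,
                      nSubpops = 3, drift = 0.15, mafFloor = 0.05,
                      nQtl = 5, qtlEffectSd = 0.8, polygenicSd = 1.8,
                      targetH2 = 0.70, bandNoiseSd = 0.01,
                      spadSlope = c(Red = -0.008, RedEdge = -0.020,
                                    Nir = 0.020, Green = -0.015,
                                    Blue = -0.006),
                      plotRows = 7, plotCols = 17, plotSizePx = 8,
                      seed = 1) {
  new("SimConfig", nGenotypes = nGenotypes, nSnps = nSnps,
      nChromosomes = nChromosomes, nSubpops = nSubpops, drift = drift,
      mafFloor = mafFloor, nQtl = nQtl, qtlEffectSd = qtlEffectSd,
      polygenicSd = polygenicSd, targetH2 = targetH2,
      bandNoiseSd = bandNoiseSd, spadSlope = spadSlope,
      plotRows = plotRows, plotCols = plotCols, plotSizePx = plotSizePx,
      seed = seed)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenotypes, "genotypes,", object@nSnps,
      "SNPs on", object@nChromosomes, "chromosomes,",
      object@nSubpops, "subpops (F =", object@drift, ")\n")
  cat("  QTLs:", object@nQtl, " effect sd:", object@qtlEffectSd,
      " target h2:", object@targetH2, " seed:", object@seed, "\n")
})

#' Synthetic genotype panel
#'
#' Biallelic dosage matrix (genotypes x markers, values 0/1/2) with a marker
#' map, subpopulation labels and the planted-QTL truth.
#'
#' @slot genotypes integer dosage matrix, rows = genotypes, cols = markers.
#' @slot map data.frame with columns marker, chrom, pos (1-based bp),
#'   positions strictly increasing within chromosome.
#' @slot subpop factor of per-genotype subpopulation labels.
#' @slot qtl data.frame with columns marker (index into the map) and effect
#'   (additive SPAD effect per dosage unit).
#' @export
setClass("WheatPopulation", representation(
  genotypes = "matrix", map = "data.frame", subpop = "factor",
  qtl = "data.frame"))

setValidity("WheatPopulation", function(object) {
  msg <- character()
  G <- object@genotypes
  if (ncol(G) != nrow(object@map))
    msg <- c(msg, "map rows must match genotype columns")
  if (nrow(G) != length(object@subpop))
    msg <- c(msg, "subpop length must match genotype rows")
  v <- G[!is.na(G)]
  if (length(v) && !all(v %in% 0:2))
    msg <- c(msg, "dosages must be in {0, 1, 2}")
  bad <- vapply(split(object@map$pos, object@map$chrom),
                function(p) any(diff(p) <= 0), logical(1))
  if (any(bad))
    msg <- c(msg, "positions must be strictly increasing within chromosome")
  if (nrow(object@qtl) && any(object@qtl$marker > ncol(G)))
    msg <- c(msg, "QTL marker index exceeds marker count")
  if (length(msg)) msg else TRUE
})

setMethod("show", "WheatPopulation", function(object) {
  cat("WheatPopulation:", nrow(object@genotypes), "genotypes x",
      ncol(object@genotypes), "markers on",
      length(unique(object@map$chrom)), "chromosomes;",
      nlevels(object@subpop), "subpopulations;",
      nrow(object@qtl), "planted QTLs\n")
})

#' @describeIn WheatPopulation dosage matrix accessor.
#' @param x,object a \code{WheatPopulation}.
#' @export
genotypes <- function(x) x@genotypes

#' @describeIn WheatPopulation marker map accessor.
#' @export
markerMap <- function(x) x@map

#' @describeIn WheatPopulation subpopulation label accessor.
#' @export
subpopLabels <- function(x) x@subpop

#' @describeIn WheatPopulation planted-QTL truth accessor.
#' @export
qtlTruth <- function(x) x@qtl

#' Replicated SPAD trial
#'
#' Long-format SPAD table keyed by (genotype, env, treatment, stage,
#' replicate), plus the replicate-free true genetic values used to generate
#' it.
#'
#' @slot spad data.frame: genotype, env, treatment, stage, replicate, spad.
#' @slot trueGenetic data.frame: genotype, env, treatment, stage, value.
#' @export
setClass("SpadTrial", representation(spad = "data.frame",
                                     trueGenetic = "data.frame"))

setValidity("SpadTrial", function(object) {
  msg <- character()
  need <- c("genotype", "env", "treatment", "stage", "replicate", "spad")
  if (!all(need %in% names(object@spad)))
    msg <- c(msg, paste("spad table must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (!all(is.finite(object@spad$spad)))
      msg <- c(msg, "SPAD values must be finite")
    reps <- tapply(object@spad$replicate,
                   interaction(object@spad$genotype, object@spad$env,
                               object@spad$treatment, object@spad$stage,
                               drop = TRUE),
                   function(r) length(unique(r)))
    if (length(reps) && min(reps) < 2)
      msg <- c(msg, "both replicates must be present for every key")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SpadTrial", function(object) {
  s <- object@spad
  cat("SpadTrial:", length(unique(s$genotype)), "genotypes x",
      length(unique(s$env)), "envs x", length(unique(s$treatment)),
      "treatments x", length(unique(s$stage)), "stages x",
      length(unique(s$replicate)), "replicates (",
      nrow(s), "rows )\n")
})

#' @describeIn SpadTrial long SPAD table accessor.
#' @param x a \code{SpadTrial}.
#' @export
spadTable <- function(x) x@spad

#' @describeIn SpadTrial true genetic value accessor.
#' @export
trueGeneticValues <- function(x) x@trueGenetic

#' Rendered five-band plot scene
#'
#' DN-valued rasters for the five bands, a whiteboard calibration rectangle,
#' and the plot layout. Rectangles are stored as inclusive pixel index ranges
#' (rowMin..rowMax, colMin..colMax), 0-based in files, 1-based in R.
#'
#' @slot bands named list of 5 numeric DN matrices (Red, RedEdge, Nir,
#'   Green, Blue).
#' @slot whiteboard integer c(rowMin, rowMax, colMin, colMax) of the
#'   whiteboard rectangle; its mean DN is within 1\% of 65000.
#' @slot plots data.frame: plot, genotype, rowMin, rowMax, colMin, colMax.
#' @slot env,treatment,stage scene key.
#' @slot truth data.frame of the generated per-plot reflectances (before
#'   pixel noise), for round-trip checks.
#' @slot clipped number of pixels clipped to [0, 1] reflectance.
#' @export
setClass("PlotScene", representation(
  bands = "list", whiteboard = "numeric", plots = "data.frame",
  env = "character", treatment = "character", stage = "character",
  truth = "data.frame", clipped = "numeric"))

setValidity("PlotScene", function(object) {
  msg <- character()
  if (!identical(names(object@bands), BAND_NAMES))
    msg <- c(msg, "bands must be named Red, RedEdge, Nir, Green, Blue")
  dims <- unique(lapply(object@bands, dim))
  if (length(dims) != 1) msg <- c(msg, "band rasters must share dimensions")
  if (any(vapply(object@bands, function(b) any(b < 0), logical(1))))
    msg <- c(msg, "DN values must be >= 0")
  wb <- object@whiteboard
  if (length(wb) == 4) {
    wbMean <- mean(object@bands[[1]][wb[1]:wb[2], wb[3]:wb[4]])
    if (abs(wbMean - 65000) > 650)
      msg <- c(msg, "whiteboard mean DN must be within 1% of 65000")
  } else msg <- c(msg, "whiteboard must be c(rowMin, rowMax, colMin, colMax)")
  p <- object@plots
  if (nrow(p) > 1) {
    o <- order(p$rowMin, p$colMin)
    p <- p[o, ]
    for (i in seq_len(nrow(p) - 1)) for (j in (i + 1):nrow(p)) {
      if (p$rowMin[j] <= p$rowMax[i] && p$rowMax[j] >= p$rowMin[i] &&
          p$colMin[j] <= p$colMax[i] && p$colMax[j] >= p$colMin[i]) {
        msg <- c(msg, "plot rectangles must be disjoint")
        break
      }
    }
  }
  if (length(msg)) unique(msg) else TRUE
})

setMethod("show", "PlotScene", function(object) {
  d <- dim(object@bands[[1]])
  cat("PlotScene [", object@env, object@treatment, object@stage, "]:",
      d[1], "x", d[2], "px x 5 bands;", nrow(object@plots), "plots;",
      object@clipped, "clipped px\n")
})

#' @describeIn PlotScene band raster accessor (named list of DN matrices).
#' @param x a \code{PlotScene}.
#' @export
sceneBands <- function(x) x@bands

#' @describeIn PlotScene plot layout accessor.
#' @export
scenePlots <- function(x) x@plots

#' @describeIn PlotScene generated per-plot reflectance truth accessor.
#' @export
sceneTruth <- function(x) x@truth

#' Backpropagation SPAD inversion model
#'
#' A single-hidden-layer feed-forward network (default 18 hidden units, tanh
#' activation, linear output) trained by full-batch gradient descent on mean
#' squared error. Features and target are standardized by training-set
#' statistics stored in the model.
#'
#' @slot featureNames input vegetation-index names, in order.
#' @slot center,scale per-feature standardization mean and sd.
#' @slot yCenter,yScale target standardization mean and sd.
#' @slot W1,b1 hidden layer weights (features x hidden) and biases.
#' @slot W2,b2 output layer weights (hidden) and bias.
#' @slot activation "tanh" or "sigmoid".
#' @slot hyperparams list(learningRate, epochs, nHidden).
#' @slot seed weight-initialization seed.
#' @slot loss per-epoch training MSE trajectory (standardized scale).
#' @export
setClass("SpadInversionModel", representation(
  featureNames = "character", center = "numeric", scale = "numeric",
  yCenter = "numeric", yScale = "numeric",
  W1 = "matrix", b1 = "numeric", W2 = "numeric", b2 = "numeric",
  activation = "character", hyperparams = "list", seed = "numeric",
  loss = "numeric"))

setValidity("SpadInversionModel", function(object) {
  msg <- character()
  p <- length(object@featureNames)
  h <- object@hyperparams$nHidden
  if (!identical(dim(object@W1), c(p, as.integer(h))) &&
      !identical(dim(object@W1), c(p, h)))
    msg <- c(msg, "W1 must be features x hidden")
  if (length(object@W2) != ncol(object@W1))
    msg <- c(msg, "W2 length must equal hidden units")
  if (length(object@b1) != ncol(object@W1))
    msg <- c(msg, "b1 length must equal hidden units")
  if (any(object@scale <= 0) || object@yScale <= 0)
    msg <- c(msg, "standardization sds must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SpadInversionModel", function(object) {
  cat("SpadInversionModel:", length(object@featureNames), "features ->",
      ncol(object@W1), "hidden (", object@activation, ") -> 1;",
      "lr", object@hyperparams$learningRate, ",",
      object@hyperparams$epochs, "epochs; final loss",
      signif(utils::tail(object@loss, 1), 4), "\n")
})
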