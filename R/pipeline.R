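# End-to-end orchestration: synthetic trial -> reflectance -> indices ->
# selection -> inversion -> trait statistics -> dual genome scans ->
# locus summaries, with a content-hashed output manifest.

trialCells <- function(trial) {
  unique(trial@spad[, c("env", "treatment", "stage")])
}

measuredMeans <- function(trial, env, treatment, stage) {
  s <- trial@spad
  sub <- s[s$env == env & s$treatment == treatment & s$stage == stage, ]
  tapply(sub$spad, sub$genotype, mean)
}

stageStep <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Generates (or reuses) a synthetic trial, renders and extracts the
#' five-band scenes, computes vegetation indices, selects features, trains
#' the inversion model per cell with the replicated 70/30 protocol, derives
#' predicted SPAD, summarizes both traits, and runs the Q+K genome scan on
#' measured and predicted values with LD-decay locus merging and overlap.
#' All declared outputs are written under \code{outputDir} and listed, with
#' md5 content hashes, in \code{manifest.json}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param outputDir output directory (created; must be empty or
#'   \code{overwrite = TRUE}).
#' @param threshold genome-scan significance threshold (default 0.001).
#' @param kTop top-importance index count for feature selection (default 5).
#' @param nReplicates inversion fitting replicates (default 8).
#' @param nnEpochs,nnLearningRate,nnHidden network hyperparameters (defaults
#'   50, 0.001, 18).
#' @param decayDefault LD-decay fallback distance, bp.
#' @param nPCs number of structure covariates (default 3).
#' @param overwrite allow writing into a non-empty directory.
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
runPipeline <- function(config = simConfig(), outputDir,
                        threshold = 0.001, kTop = 5, nReplicates = 8,
                        nnEpochs = 50, nnLearningRate = 0.001,
                        nnHidden = 18, decayDefault = 5e6, nPCs = 3,
                        overwrite = FALSE) {
  if (dir.exists(outputDir) && length(dir(outputDir)) && !overwrite)
    stopf("output directory '%s' is not empty (use overwrite = TRUE)",
          outputDir)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)

  pop <- stageStep("simulate-genotypes", simulateGenotypes(config))
  trial <- stageStep("simulate-phenotypes",
                     simulateSpadPhenotypes(pop, config))
  cells <- trialCells(trial)

  plotRefl <- stageStep("reflectance", {
    do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      sc <- renderScene(trial, cells$env[i], cells$treatment[i],
                        cells$stage[i], config)
      extractPlotReflectance(sc)
    }))
  })
  bandSummary <- stageStep("band-summary", bandStageSummary(plotRefl))
  vi <- stageStep("vegindex", computeAllVI(plotRefl))

  selection <- list()
  importanceRows <- fitRows <- predRows <- list()
  stageStep("featsel-inversion", {
    for (i in seq_len(nrow(cells))) {
      key <- cells[i, ]
      cellVI <- vi[vi$env == key$env & vi$treatment == key$treatment &
                   vi$stage == key$stage, ]
      spadM <- measuredMeans(trial, key$env, key$treatment, key$stage)
      spadM <- spadM[match(cellVI$genotype, names(spadM))]
      imp <- rfImportance(cellVI, spadM, seed = config@seed + i)
      rr <- correlateWithSpad(cellVI, spadM)
      sel <- selectIndices(imp, rr, kTop = kTop)
      tag <- paste(key$env, key$treatment, key$stage, sep = "_")
      selection[[tag]] <- as.character(sel)
      importanceRows[[tag]] <- data.frame(
        env = key$env, treatment = key$treatment, stage = key$stage,
        index = names(imp), importance = as.numeric(imp),
        pearson_r = as.numeric(rr[names(imp)]), stringsAsFactors = FALSE)
      feats <- cellVI[, as.character(sel), drop = FALSE]
      rep <- replicateFit(feats, spadM, nReplicates = nReplicates,
                          seed = config@seed + 100 + i,
                          nHidden = nnHidden, epochs = nnEpochs,
                          learningRate = nnLearningRate)
      fitRows[[tag]] <- cbind(env = key$env, treatment = key$treatment,
                               stage = key$stage, as.data.frame(rep))
      model <- trainInversionModel(feats, spadM, nHidden = nnHidden,
                                   epochs = nnEpochs,
                                   learningRate = nnLearningRate,
                                   seed = config@seed + 200 + i)
      predRows[[tag]] <- data.frame(
        genotype = cellVI$genotype, env = key$env,
        treatment = key$treatment, stage = key$stage, replicate = 1L,
        value = predictSpad(model, feats), source = "predicted",
        stringsAsFactors = FALSE)
    }
  })

  traits <- stageStep("traitstats", {
    meas <- trial@spad
    meas <- data.frame(genotype = meas$genotype, env = meas$env,
                       treatment = meas$treatment, stage = meas$stage,
                       replicate = meas$replicate, value = meas$spad,
                       source = "measured", stringsAsFactors = FALSE)
    rbind(meas, do.call(rbind, predRows))
  })
  traitSummary <- stageStep("trait-summary", summarizeTraitTable(traits))

  G <- genotypes(pop)
  K <- stageStep("kinship", computeKinship(G))
  Qm <- stageStep("structure-pca", computeQ(G, q = nPCs))
  decay <- stageStep("ld-decay",
                     estimateLdDecay(G, markerMap(pop),
                                     default = decayDefault))

  assoc <- list(); lociList <- list(); overlaps <- list()
  stageStep("gwas", {
    for (i in seq_len(nrow(cells))) {
      key <- cells[i, ]
      perSource <- list()
      for (src in c("measured", "predicted")) {
        y <- if (src == "measured")
          measuredMeans(trial, key$env, key$treatment, key$stage)
        else {
          pr <- predRows[[paste(key$env, key$treatment, key$stage,
                                sep = "_")]]
          stats::setNames(pr$value, pr$genotype)
        }
        y <- y[match(rownames(G), names(y))]
        res <- mlmScan(y, G, K, Qm, markerMap(pop))
        res <- cbind(res, env = key$env, treatment = key$treatment,
                     stage = key$stage, source = src)
        assoc[[paste(key$env, key$treatment, key$stage, src,
                     sep = "_")]] <- res
        sig <- filterSignificant(res, threshold)
        perSource[[src]] <- mergeLoci(sig, as.numeric(decay))
      }
      lociList[[paste(key$env, key$treatment, key$stage,
                      "measured", sep = "_")]] <- perSource$measured
      lociList[[paste(key$env, key$treatment, key$stage,
                      "predicted", sep = "_")]] <- perSource$predicted
      ov <- overlapLoci(perSource$measured, perSource$predicted,
                        window = as.numeric(decay))
      if (nrow(ov))
        overlaps[[length(overlaps) + 1]] <-
          cbind(env = key$env, treatment = key$treatment,
                stage = key$stage, ov)
    }
  })

  lociTable <- do.call(rbind, lapply(lociList, function(gr)
    if (length(gr)) lociToTable(gr) else NULL))
  rownames(lociTable) <- NULL
  locusSummary <- stageStep("locus-summary", {
    if (!is.null(lociTable) && nrow(lociTable))
      summarizeLoci(lociTable, by = c("treatment", "stage", "source"))
    else list(cells = NULL,
              overall = data.frame(source = "total", n = 0,
                                   mean_p = NA_real_,
                                   mean_r2_pct = NA_real_))
  })
  overlapTable <- if (length(overlaps)) do.call(rbind, overlaps) else
    data.frame()
  assocTable <- do.call(rbind, assoc)
  rownames(assocTable) <- NULL
  manhattan <- data.frame(marker = assocTable$marker,
                          chrom = assocTable$chrom, pos = assocTable$pos,
                          env = assocTable$env,
                          treatment = assocTable$treatment,
                          stage = assocTable$stage,
                          source = assocTable$source,
                          neg_log10_p = -log10(assocTable$p))

  stageStep("write-outputs", {
    wr <- function(x, f) utils::write.csv(x, file.path(outputDir, f),
                                          row.names = FALSE)
    wr(plotRefl, "plot_reflectance.csv")
    wr(bandSummary, "band_stage_summary.csv")
    wr(as.data.frame(vi), "vegindex.csv")
    wr(do.call(rbind, importanceRows), "importance.csv")
    jsonlite::write_json(selection, file.path(outputDir, "selection.json"),
                         auto_unbox = FALSE, pretty = TRUE)
    wr(do.call(rbind, fitRows), "fit_report.csv")
    wr(traitSummary, "trait_summary.csv")
    wr(assocTable, "assoc.csv")
    if (!is.null(lociTable)) wr(lociTable, "loci.csv")
    wr(overlapTable, "overlap.csv")
    if (!is.null(locusSummary$cells))
      wr(locusSummary$cells, "locus_summary_cells.csv")
    wr(locusSummary$overall, "locus_summary.csv")
    wr(manhattan, "manhattan.csv")
  })

  files <- sort(setdiff(dir(outputDir), "manifest.json"))
  manifest <- list(
    parameters = list(seed = config@seed, nGenotypes = config@nGenotypes,
                      nSnps = config@nSnps, threshold = threshold,
                      kTop = kTop, nReplicates = nReplicates,
                      nnEpochs = nnEpochs, nnLearningRate = nnLearningRate,
                      nnHidden = nnHidden, nPCs = nPCs,
                      ldDecay = as.numeric(decay)),
    files = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(outputDir, f)))))
  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(population = pop, trial = trial, plotRefl = plotRefl,
                 bandSummary = bandSummary, vi = vi, selection = selection,
                 fitReport = do.call(rbind, fitRows), traits = traits,
                 traitSummary = traitSummary, kinship = K, Q = Qm,
                 ldDecay = decay, assoc = assocTable, loci = lociList,
                 lociTable = lociTable, overlap = overlapTable,
                 locusSummary = locusSummary, manifest = manifest))
}

#' Write the synthetic fixture bundle
#'
#' Renders and writes everything \code{\link{runPipeline}} can consume from
#' disk: one multiband 16-bit TIFF per scene (band order Red, RedEdge, Nir,
#' Green, Blue), plots.csv (plot id, genotype, inclusive pixel rectangle,
#' scene key), spad.csv (long trial table), genotypes.csv + map.csv, and
#' truth.json (planted QTLs and seed).
#'
#' @param config a \linkS4class{SimConfig}.
#' @param dir output directory.
#' @param overwrite allow writing into a non-empty directory.
#' @return Invisibly, the vector of written file paths.
#' @export
makeFixtures <- function(config, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) && !overwrite)
    stopf("fixture directory '%s' is not empty (use overwrite = TRUE)", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pop <- simulateGenotypes(config)
  trial <- simulateSpadPhenotypes(pop, config)
  cells <- trialCells(trial)
  written <- character(0)
  plotsAll <- list()
  for (i in seq_len(nrow(cells))) {
    sc <- renderScene(trial, cells$env[i], cells$treatment[i],
                      cells$stage[i], config)
    tag <- paste(cells$env[i], cells$treatment[i], cells$stage[i],
                 sep = "_")
    f <- file.path(dir, paste0("scene_", tag, ".tif"))
    tiff::writeTIFF(lapply(sc@bands, function(m) round(m) / 65535),
                    f, bits.per.sample = 16, compression = "none")
    written <- c(written, f)
    p <- sc@plots
    p$env <- cells$env[i]; p$treatment <- cells$treatment[i]
    p$stage <- cells$stage[i]
    plotsAll[[tag]] <- p
  }
  wr <- function(x, f) {
    path <- file.path(dir, f)
    utils::write.csv(x, path, row.names = FALSE)
    written <- c(written, path)
  }
  wr(do.call(rbind, plotsAll), "plots.csv")
  wr(trial@spad, "spad.csv")
  g <- data.frame(genotype = rownames(genotypes(pop)), genotypes(pop),
                  check.names = FALSE)
  wr(g, "genotypes.csv")
  wr(markerMap(pop), "map.csv")
  jsonlite::write_json(list(seed = config@seed,
                            qtl = qtlTruth(pop)),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  written <- c(written, file.path(dir, "truth.json"))
  invisible(written)
}

#' Read a fixture scene TIFF back as a DN band list
#'
#' @param path multiband TIFF written by \code{\link{makeFixtures}}.
#' @return Named list of 5 DN matrices (Red, RedEdge, Nir, Green, Blue).
#' @export
readSceneTIFF <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  stats::setNames(lapply(frames, function(m) m * 65535), BAND_NAMES)
}
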