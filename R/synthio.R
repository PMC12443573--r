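# Synthetic-data generators: genotypes with population structure, replicated
# SPAD trials with planted QTLs, and five-band DN scenes.

# Scene-wide band reflectance baselines (fractions) per treatment x stage,
# taken from the study-scale band means so that rendered scenes reproduce
# realistic magnitudes and the Nir > RedEdge > Green > Red > Blue ordering.
bandBaselines <- function() {
  t3 <- table3Reflectance()
  t3$reflectance <- t3$reflectance_pct / 100
  t3
}

lookupBaseline <- function(baselines, treatment, stage) {
  rows <- baselines[baselines$treatment == treatment &
                    baselines$stage == stage, ]
  stats::setNames(rows$reflectance[match(BAND_NAMES, rows$band)], BAND_NAMES)
}

#' Simulate a structured genotype panel
#'
#' Draws biallelic dosages under a Balding-Nichols model: ancestral allele
#' frequencies are uniform on (0.1, 0.9), subpopulation frequencies are Beta
#' distributed around them with drift parameter F, and dosages are binomial.
#' Markers failing the minor-allele-frequency floor are dropped before the
#' requested panel size is taken. Planted QTLs are sampled among markers with
#' MAF >= 0.1 so their effects are detectable.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return A \linkS4class{WheatPopulation}.
#' @examples
#' pop <- simulateGenotypes(simConfig(nGenotypes = 40, nSnps = 200, seed = 1))
#' @export
simulateGenotypes <- function(config) {
  validObject(config)
  withSeed(config@seed, {
    n <- config@nGenotypes
    mWant <- config@nSnps
    mDraw <- ceiling(mWant * 1.4) + 100
    pAnc <- stats::runif(mDraw, 0.1, 0.9)
    k <- config@nSubpops
    subpop <- factor(rep_len(paste0("P", seq_len(k)), n))
    fF <- config@drift
    pSub <- matrix(pAnc, nrow = k, ncol = mDraw, byrow = TRUE)
    if (fF > 0 && k > 1) {
      a <- pAnc * (1 - fF) / fF
      b <- (1 - pAnc) * (1 - fF) / fF
      for (s in seq_len(k))
        pSub[s, ] <- stats::rbeta(mDraw, a, b)
    }
    G <- matrix(0L, n, mDraw)
    for (s in seq_len(k)) {
      idx <- which(as.integer(subpop) == s)
      G[idx, ] <- matrix(stats::rbinom(length(idx) * mDraw, 2L,
                                       rep(pSub[s, ], each = length(idx))),
                         nrow = length(idx))
    }
    p <- colMeans(G) / 2
    maf <- pmin(p, 1 - p)
    keep <- which(maf >= config@mafFloor)
    if (!length(keep))
      stopf("no polymorphic markers remain after MAF filtering (floor %.3f)",
            config@mafFloor)
    if (length(keep) < mWant) {
      warnf("only %d of %d requested markers passed the MAF floor",
            length(keep), mWant)
      mWant <- length(keep)
    }
    keep <- keep[seq_len(mWant)]
    G <- G[, keep, drop = FALSE]
    maf <- maf[keep]

    chroms <- wheatChromosomes(config@nChromosomes)
    chrom <- sort(rep_len(seq_along(chroms), mWant))
    pos <- unlist(lapply(split(seq_len(mWant), chrom), function(ix)
      sort(sample.int(6e8, length(ix)))), use.names = FALSE)
    map <- data.frame(marker = sprintf("SNP%05d", seq_len(mWant)),
                      chrom = chroms[chrom], pos = pos,
                      stringsAsFactors = FALSE)
    colnames(G) <- map$marker
    rownames(G) <- sprintf("G%03d", seq_len(n))

    qtl <- data.frame(marker = integer(0), effect = numeric(0))
    if (config@nQtl > 0) {
      cand <- which(maf >= 0.1)
      if (length(cand) < config@nQtl) cand <- seq_len(mWant)
      idx <- sort(sample(cand, config@nQtl))
      qtl <- data.frame(marker = idx,
                        effect = stats::rnorm(config@nQtl, 0,
                                              config@qtlEffectSd))
    }
    new("WheatPopulation", genotypes = G, map = map, subpop = subpop,
        qtl = qtl)
  })
}

# Stage/treatment SPAD baselines: means rise from heading to grain filling
# and drought runs slightly higher late, mirroring the emulated trial.
spadBaseline <- function(env, treatment, stage) {
  base <- c(HS = 54.4, FL = 55.4, GF = 56.3)[stage]
  if (treatment == "D") base <- base + c(HS = 0.1, FL = 0.6, GF = 1.5)[stage]
  if (env == "E2") base <- base + 0.5
  unname(base)
}

#' Simulate replicated SPAD phenotypes
#'
#' Forward model: SPAD = stage/treatment/environment baseline + planted QTL
#' effects on centered dosages + a polygenic term + i.i.d. replicate noise.
#' The replicate noise variance is set from the realized genetic variance so
#' that the expected broad-sense heritability equals \code{targetH2}.
#'
#' @param pop a \linkS4class{WheatPopulation}.
#' @param config the \linkS4class{SimConfig} used to generate \code{pop}.
#' @return A \linkS4class{SpadTrial} with two replicates per key.
#' @examples
#' cfg <- simConfig(nGenotypes = 40, nSnps = 200, seed = 1)
#' trial <- simulateSpadPhenotypes(simulateGenotypes(cfg), cfg)
#' @export
simulateSpadPhenotypes <- function(pop, config) {
  validObject(config)
  if (config@targetH2 >= 1)
    stopf("targetH2 = 1 is inestimable with replicate noise present")
  if (nrow(pop@qtl) == 0 && config@polygenicSd == 0 && config@targetH2 > 0)
    stopf("no genetic variance source: plant QTLs or set targetH2 = 0")
  withSeed(config@seed + 1L, {
    G <- pop@genotypes
    n <- nrow(G)
    g <- numeric(n)
    if (config@targetH2 > 0) {
      if (nrow(pop@qtl)) {
        Zq <- scale(G[, pop@qtl$marker, drop = FALSE], scale = FALSE)
        g <- g + drop(Zq %*% pop@qtl$effect)
      }
      if (config@polygenicSd > 0) {
        bg <- setdiff(seq_len(ncol(G)), pop@qtl$marker)
        Zb <- scale(G[, bg, drop = FALSE], scale = FALSE)
        u <- drop(Zb %*% stats::rnorm(length(bg)))
        if (stats::sd(u) > 0) u <- u / stats::sd(u) * config@polygenicSd
        g <- g + u
      }
    }
    varG <- stats::var(g)
    noiseSd <- if (config@targetH2 == 0 || varG == 0) 2.5 else
      sqrt(varG * (1 - config@targetH2) / config@targetH2)

    keys <- expand.grid(genotype = rownames(G), env = ENVS,
                        treatment = TREATMENTS, stage = STAGES,
                        stringsAsFactors = FALSE)
    keys$value <- mapply(spadBaseline, keys$env, keys$treatment, keys$stage) +
      g[match(keys$genotype, rownames(G))]

    spad <- rbind(transform(keys, replicate = 1L),
                  transform(keys, replicate = 2L))
    spad$spad <- spad$value + stats::rnorm(nrow(spad), 0, noiseSd)
    spad$value <- NULL
    rownames(spad) <- NULL
    new("SpadTrial", spad = spad,
        trueGenetic = keys[, c("genotype", "env", "treatment", "stage",
                               "value")])
  })
}

#' Render a five-band DN scene for one trial cell
#'
#' Plots are laid out on a rectangular grid with a reserved whiteboard
#' rectangle (reflectance 0.998, DN 65000). Per-plot band reflectance is an
#' affine function of the plot's replicate-mean SPAD (standardized within the
#' scene): visible-band reflectance decreases with SPAD, near-infrared
#' increases, at the per-sd slopes in \code{config@spadSlope}. Per-pixel
#' Gaussian noise (sd \code{bandNoiseSd}) is added on the reflectance scale;
#' values outside [0, 1] are clipped and counted. DN = reflectance x
#' 65000 / 0.998.
#'
#' @param trial a \linkS4class{SpadTrial}.
#' @param env,treatment,stage the scene key; must be present in the trial.
#' @param config a \linkS4class{SimConfig}.
#' @return A \linkS4class{PlotScene}.
#' @examples
#' cfg <- simConfig(nGenotypes = 12, nSnps = 100, plotRows = 3, plotCols = 4)
#' trial <- simulateSpadPhenotypes(simulateGenotypes(cfg), cfg)
#' sc <- renderScene(trial, "E1", "W", "HS", cfg)
#' @export
renderScene <- function(trial, env, treatment, stage, config) {
  s <- trial@spad
  cell <- s[s$env == env & s$treatment == treatment & s$stage == stage, ]
  if (!nrow(cell))
    stopf("key (%s, %s, %s) not present in trial", env, treatment, stage)
  spadMean <- tapply(cell$spad, cell$genotype, mean)
  genos <- names(spadMean)
  z <- if (stats::sd(spadMean) > 0)
    (spadMean - mean(spadMean)) / stats::sd(spadMean) else spadMean * 0

  withSeed(config@seed + 7L +
           match(env, ENVS) * 100L + match(treatment, TREATMENTS) * 10L +
           match(stage, STAGES), {
    base <- lookupBaseline(bandBaselines(), treatment, stage)
    slope <- config@spadSlope
    nG <- length(genos)
    sz <- config@plotSizePx
    gap <- 2L
    wbRows <- 6L
    nRow <- config@plotRows
    nCol <- config@plotCols
    H <- wbRows + gap + nRow * (sz + gap)
    W <- max(nCol * (sz + gap) + gap, 12L)

    plots <- data.frame(plot = paste0("plot_", seq_len(nG)),
                        genotype = genos, stringsAsFactors = FALSE)
    idx <- seq_len(nG) - 1L
    pr <- idx %/% nCol
    pc <- idx %% nCol
    plots$rowMin <- wbRows + gap + pr * (sz + gap) + 1L
    plots$rowMax <- plots$rowMin + sz - 1L
    plots$colMin <- gap + pc * (sz + gap) + 1L
    plots$colMax <- plots$colMin + sz - 1L

    truth <- data.frame(plot = plots$plot, genotype = genos,
                        stringsAsFactors = FALSE)
    for (b in BAND_NAMES)
      truth[[REFL_COLS[[b]]]] <- base[[b]] + slope[[b]] * unname(z)

    clipped <- 0L
    bands <- list()
    for (b in BAND_NAMES) {
      refl <- matrix(0.05, H, W)                       # soil background
      refl[1:wbRows, 1:min(10L, W)] <- 0.998           # whiteboard
      for (i in seq_len(nG))
        refl[plots$rowMin[i]:plots$rowMax[i],
             plots$colMin[i]:plots$colMax[i]] <- truth[[REFL_COLS[[b]]]][i]
      if (config@bandNoiseSd > 0)
        refl <- refl + matrix(stats::rnorm(H * W, 0, config@bandNoiseSd),
                              H, W)
      out <- refl < 0 | refl > 1
      clipped <- clipped + sum(out)
      refl[refl < 0] <- 0
      refl[refl > 1] <- 1
      bands[[b]] <- refl * 65000 / 0.998
    }
    if (clipped > 0)
      message(sprintf("renderScene: clipped %d pixels to [0, 1] reflectance",
                      clipped))
    new("PlotScene", bands = bands,
        whiteboard = c(1, wbRows, 1, min(10L, W)),
        plots = plots, env = env, treatment = treatment, stage = stage,
        truth = truth, clipped = as.numeric(clipped))
  })
}
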