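# Shared fixture builders; everything is generated in code under fixed seeds.

tinyConfig <- function(seed = 1, ...) {
  args <- list(nGenotypes = 40, nSnps = 300, seed = seed,
               plotRows = 5, plotCols = 8)
  args[names(list(...))] <- list(...)
  do.call(simConfig, args)
}

# genotypes in perfect-LD blocks of physical size `d`, adjacent blocks
# contiguous along the chromosome and independent of each other
blockGenotypes <- function(seed, d = 4e6, nInd = 80, nBlocks = 12,
                           mPerBlock = 6, chroms = paste0(1:3, "A")) {
  set.seed(seed)
  G <- NULL
  map <- NULL
  for (cn in chroms) for (b in seq_len(nBlocks)) {
    hap <- rbinom(nInd, 2, runif(1, 0.2, 0.8))
    start <- (b - 1) * d
    pos <- sort(sample(seq(start + 1, start + d), mPerBlock))
    G <- cbind(G, matrix(rep(hap, mPerBlock), nInd))
    map <- rbind(map, data.frame(marker = paste(cn, b, seq_len(mPerBlock),
                                                sep = "_"),
                                 chrom = cn, pos = pos))
  }
  colnames(G) <- map$marker
  list(G = G, map = map)
}

# measured genotype means for one trial cell, aligned to the population rows
cellMeans <- function(trial, pop, env = "E1", treatment = "W",
                      stage = "HS") {
  s <- spadTable(trial)
  sub <- s[s$env == env & s$treatment == treatment & s$stage == stage, ]
  y <- tapply(sub$spad, sub$genotype, mean)
  y[match(rownames(genotypes(pop)), names(y))]
}

# direct transcription of the 18 index formulas, kept independent of the
# package's dispatch table for oracle comparisons
viOracle <- function(b) {
  Red <- b[["Red"]]; RE <- b[["RedEdge"]]; Nir <- b[["Nir"]]
  Green <- b[["Green"]]; Blue <- b[["Blue"]]
  c(NDVI = (Nir - Red) / (Nir + Red),
    GNDVI = (Nir - Green) / (Nir + Green),
    NGBDI = (Green - Blue) / (Green + Blue),
    NGRDI = (Green - Red) / (Green + Red),
    RERDVI = (Nir - RE) / (Nir + RE),
    SAVI = 2.5 * (Nir - Red) / (Nir + Red + 0.5),
    GOSAVI = 1.16 * ((Nir - Green) / (Nir + Green + 0.16)),
    REOSAVI = 1.16 * ((Nir - Red) / (Nir + Red + 0.16)),
    OSAVI = (Nir - Red) / (Nir + Red + 0.16),
    RVI = Nir / Red,
    DVI = Nir - Red,
    GRVI = Nir / Green,
    EXG = 2 * Green - Red - Blue,
    TVI = 0.5 * (120 * (Nir - Green) - 200 * (Red - Green)),
    CARI = (RE - Red) / (0.2 * (RE + Red)),
    VARIgreen = (Green - Red) / (Green + Red - Blue),
    VARIred = (RE - 1.7 * Red + 0.7 * Blue) /
      (RE + 2.3 * Red - 1.3 * Blue),
    EVI = 2.5 * (Nir - Red) / (Nir + 6 * Red - 7.5 * Blue + 1))
}

# brute-force single-linkage 1D clustering oracle
bruteMerge <- function(pos, dmax) {
  n <- length(pos)
  cl <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (cl[i] != cl[j] && abs(pos[i] - pos[j]) <= dmax) {
        cl[cl == cl[j]] <- cl[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(cl, unique(cl))
}
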