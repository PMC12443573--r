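test_that("kinship matches a brute-force oracle and handles duplicates", {
  for (s in 1:3) {
    set.seed(s)
    G <- matrix(rbinom(10 * 50, 2, runif(50, 0.1, 0.9)), 10, 50,
                byrow = TRUE)
    K <- computeKinship(G)
    # brute-force double loop
    p <- colMeans(G) / 2
    poly <- p > 0 & p < 1
    Gp <- G[, poly, drop = FALSE]; pp <- p[poly]
    denom <- 2 * sum(pp * (1 - pp))
    oracle <- matrix(0, 10, 10)
    for (i in 1:10) for (j in 1:10)
      oracle[i, j] <- sum((Gp[i, ] - 2 * pp) * (Gp[j, ] - 2 * pp)) / denom
    expect_lt(max(abs(K - oracle)), 1e-10)
    expect_true(isSymmetric(K))
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
  # duplicated individuals have K_ij = K_ii = K_jj
  set.seed(4)
  G <- matrix(rbinom(8 * 40, 2, 0.4), 8, 40)
  G[2, ] <- G[1, ]
  K <- computeKinship(G)
  expect_equal(K[1, 2], K[1, 1])
  expect_equal(K[1, 2], K[2, 2])
  expect_error(computeKinship(matrix(2, 5, 3)), "polymorphic")
})

test_that("structure covariates are centered, orthogonal PCs that separate subpopulations", {
  cfg <- tinyConfig(seed = 12, nGenotypes = 60, nSnps = 800, drift = 0.25,
                    plotRows = 6, plotCols = 10)
  pop <- simulateGenotypes(cfg)
  Q <- computeQ(genotypes(pop), q = 3)
  expect_lt(max(abs(colMeans(Q))), 1e-10)
  cp <- crossprod(Q)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
  lab <- as.integer(subpopLabels(pop))
  d <- as.matrix(dist(Q[, 1:2]))
  sil <- vapply(seq_along(lab), function(i) {
    a <- mean(d[i, lab == lab[i] & seq_along(lab) != i])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(k) mean(d[i, lab == k]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
  expect_error(computeQ(genotypes(pop)[1:3, ], q = 3), "q must be <")
})

test_that("the mixed scan reduces to OLS when K = I and Q is empty", {
  set.seed(21)
  n <- 30; m <- 50
  G <- matrix(rbinom(n * m, 2, 0.4), n, m,
              dimnames = list(NULL, paste0("m", 1:m)))
  y <- rnorm(n)
  res <- mlmScan(y, G, K = NULL, Q = NULL, mafFloor = 0)
  resI <- mlmScan(y, G, K = diag(n), Q = NULL, mafFloor = 0)
  ols <- vapply(1:m, function(j) {
    if (sd(G[, j]) == 0) return(NA_real_)
    summary(lm(y ~ G[, j]))$coefficients[2, 4]
  }, numeric(1))
  expect_lt(max(abs(res$p - ols), na.rm = TRUE), 1e-8)
  expect_lt(max(abs(resI$p - ols), na.rm = TRUE), 1e-8)
})

test_that("a perfectly explanatory marker attains the minimum P and full marker R2", {
  set.seed(22)
  G <- matrix(rbinom(40 * 60, 2, 0.5), 40, 60,
              dimnames = list(NULL, paste0("m", 1:60)))
  y <- 2.5 * G[, 17]
  res <- mlmScan(y, G, mafFloor = 0)
  expect_equal(res$marker[which.min(res$p)], "m17")
  expect_gte(res$markerR2[res$marker == "m17"], 0.99)
})

test_that("significance filtering is strict at the threshold", {
  res <- data.frame(marker = paste0("m", 1:4), chrom = "1A",
                    pos = 1:4, effect = 0, se = 1,
                    p = c(0.001, 0.0009999, 0.5, NA), markerR2 = 0.1)
  sig <- filterSignificant(res, 0.001)
  expect_equal(sig$marker, "m2")        # P = 0.001 exactly is excluded
  none <- filterSignificant(res, 1e-10)
  expect_equal(nrow(none), 0)
  # count oracle on random P values
  set.seed(9)
  res2 <- data.frame(marker = paste0("x", 1:500), chrom = "1A",
                     pos = 1:500, effect = 0, se = 1,
                     p = runif(500, 0, 0.01), markerR2 = 0)
  expect_equal(nrow(filterSignificant(res2, 0.001)),
               sum(res2$p < 0.001))
})

test_that("the Q+K model controls structured confounding that a naive scan does not", {
  # null phenotype driven only by subpopulation shifts
  lamQK <- c(); lamNaive <- c()
  for (s in 1:8) {
    cfg <- simConfig(nGenotypes = 100, nSnps = 1000, seed = s, nQtl = 0,
                     targetH2 = 0, plotRows = 10, plotCols = 10)
    pop <- simulateGenotypes(cfg)
    G <- genotypes(pop)
    set.seed(1000 + s)
    y <- c(0, 1.5, 3)[as.integer(subpopLabels(pop))] + rnorm(nrow(G))
    K <- computeKinship(G)
    Q <- computeQ(G, 3)
    res <- mlmScan(y, G, K, Q, markerMap(pop))
    lamQK <- c(lamQK, median(qchisq(1 - res$p, 1), na.rm = TRUE) /
                 qchisq(0.5, 1))
    resN <- mlmScan(y, G, K = NULL, Q = NULL, markerMap(pop))
    lamNaive <- c(lamNaive, median(qchisq(1 - resN$p, 1), na.rm = TRUE) /
                    qchisq(0.5, 1))
  }
  expect_gte(mean(lamQK), 0.9)
  expect_lte(mean(lamQK), 1.15)
  expect_gt(mean(lamNaive), 1.2)
})

test_that("LD decay is recovered from block-structured genotypes", {
  bl <- blockGenotypes(seed = 7, d = 4e6)
  est <- estimateLdDecay(bl$G, bl$map)
  expect_gte(as.numeric(est), 0.5 * 4e6)
  expect_lte(as.numeric(est), 2 * 4e6)
  expect_true(attr(est, "crossed"))
  # deterministic given fixed input
  expect_identical(as.numeric(estimateLdDecay(bl$G, bl$map)),
                   as.numeric(est))
  # perfect LD everywhere: never crosses, returns max distance flagged
  set.seed(5)
  hap <- rbinom(50, 2, 0.5)
  G2 <- matrix(rep(hap, 30), 50)
  map2 <- data.frame(marker = paste0("m", 1:30),
                     chrom = rep(c("1A", "2A"), each = 15),
                     pos = rep(seq(1e6, 15e6, 1e6), 2))
  est2 <- estimateLdDecay(G2, map2)
  expect_false(attr(est2, "crossed"))
  expect_equal(as.numeric(est2), 14e6)
  # too few pairs falls back to the default with a warning
  expect_warning(out <- estimateLdDecay(G2[, 1:4], map2[1:4, ],
                                        default = 3e6),
                 "default")
  expect_equal(as.numeric(out), 3e6)
})

test_that("locus merging matches a brute-force single-linkage oracle", {
  sig <- data.frame(marker = paste0("m", 1:3), chrom = "5B",
                    pos = c(1.0e6, 1.5e6, 10e6), effect = 0, se = 1,
                    p = c(1e-4, 5e-5, 2e-6), markerR2 = c(0.1, 0.12, 0.2))
  loci <- mergeLoci(sig, 2e6)
  expect_length(loci, 2)
  lt <- lociToTable(loci)
  expect_equal(sort(lt$nMarkers), c(1, 2))
  expect_equal(lt$marker[lt$nMarkers == 2], "m2")   # min P among members

  # empty input
  expect_length(mergeLoci(sig[0, ], 2e6), 0)

  # all markers in one window, representative = min P (ties -> smaller bp)
  sig2 <- data.frame(marker = paste0("m", 1:4), chrom = "1A",
                     pos = c(10, 20, 30, 40) * 1e3, effect = 0, se = 1,
                     p = c(1e-5, 1e-6, 1e-6, 1e-4), markerR2 = 0.1)
  l2 <- mergeLoci(sig2, 5e4)
  expect_length(l2, 1)
  expect_equal(lociToTable(l2)$marker, "m2")

  # randomized comparison against the brute-force clustering oracle
  set.seed(14)
  for (i in 1:10) {
    nSig <- sample(5:25, 1)
    sigR <- data.frame(marker = paste0("m", seq_len(nSig)),
                       chrom = sample(c("1A", "2B"), nSig, TRUE),
                       pos = sample.int(5e7, nSig), effect = 0, se = 1,
                       p = runif(nSig, 1e-8, 1e-3),
                       markerR2 = runif(nSig, 0.05, 0.3))
    dmax <- sample.int(1e7, 1)
    loci <- mergeLoci(sigR, dmax)
    nOracle <- sum(vapply(split(sigR$pos, sigR$chrom), function(p)
      length(unique(bruteMerge(p, dmax))), integer(1)))
    expect_length(loci, nOracle)
  }

  # idempotence: merging the representatives changes nothing
  lt3 <- lociToTable(mergeLoci(sig, 2e6))
  again <- mergeLoci(data.frame(marker = lt3$marker, chrom = lt3$chrom,
                                pos = lt3$pos, p = lt3$p,
                                markerR2 = lt3$marker_r2_pct / 100),
                     2e6)
  expect_length(again, nrow(lt3))
  expect_setequal(lociToTable(again)$marker, lt3$marker)
})

test_that("overlap pairing is greedy, chromosome-bound and oracle-consistent", {
  t6 <- table6OverlapLoci()
  meas <- mergeLoci(transform(t6[t6$source == "measured", ],
                              markerR2 = marker_r2_pct / 100), 1e6)
  pred <- mergeLoci(transform(t6[t6$source == "predicted", ],
                              markerR2 = marker_r2_pct / 100), 1e6)
  ov <- overlapLoci(meas, pred, window = 5e6)
  # the shared representative marker pairs at distance zero
  shared <- ov[ov$measuredMarker == "AX-179557826", ]
  expect_equal(nrow(shared), 1)
  expect_equal(shared$predictedMarker, "AX-179557826")
  expect_equal(shared$distance, 0)
  expect_true(all(ov$distance <= 5e6))
  # each locus appears in at most one pair
  expect_false(any(duplicated(ov$measuredMarker)))
  expect_false(any(duplicated(ov$predictedMarker)))

  # different chromosomes never pair
  a <- mergeLoci(data.frame(marker = "a", chrom = "1A", pos = 100,
                            p = 1e-5, markerR2 = 0.1), 1e3)
  b <- mergeLoci(data.frame(marker = "b", chrom = "2A", pos = 100,
                            p = 1e-5, markerR2 = 0.1), 1e3)
  expect_equal(nrow(overlapLoci(a, b, window = 1e9)), 0)

  # pairing count equals a brute-force bipartite greedy oracle
  set.seed(15)
  for (i in 1:10) {
    nm <- sample(3:10, 1); np <- sample(3:10, 1)
    mT <- data.frame(marker = paste0("M", seq_len(nm)), chrom = "3B",
                     pos = sample.int(1e7, nm), p = runif(nm, 1e-6, 1e-3),
                     markerR2 = 0.1)
    pT <- data.frame(marker = paste0("P", seq_len(np)), chrom = "3B",
                     pos = sample.int(1e7, np), p = runif(np, 1e-6, 1e-3),
                     markerR2 = 0.1)
    win <- 2e6
    got <- overlapLoci(mergeLoci(mT, 1), mergeLoci(pT, 1), window = win)
    # oracle: greedy over the sorted distance list
    dd <- expand.grid(i = seq_len(nm), j = seq_len(np))
    dd$dist <- abs(mT$pos[dd$i] - pT$pos[dd$j])
    dd <- dd[dd$dist <= win, ]
    dd <- dd[order(dd$dist, dd$i, dd$j), ]
    um <- up <- c(); cnt <- 0
    for (k in seq_len(nrow(dd))) {
      if (dd$i[k] %in% um || dd$j[k] %in% up) next
      um <- c(um, dd$i[k]); up <- c(up, dd$j[k]); cnt <- cnt + 1
    }
    expect_equal(nrow(got), cnt)
  }
})

test_that("planted QTLs are recovered by the merged loci in most runs", {
  hits <- 0; tot <- 0
  for (s in 1:20) {
    cfg <- simConfig(nGenotypes = 119, nSnps = 1000, seed = s, nQtl = 3,
                     qtlEffectSd = 3, polygenicSd = 1.5, targetH2 = 0.7)
    pop <- simulateGenotypes(cfg)
    trial <- simulateSpadPhenotypes(pop, cfg)
    y <- cellMeans(trial, pop)
    G <- genotypes(pop)
    res <- mlmScan(y, G, computeKinship(G), computeQ(G, 3), markerMap(pop))
    decay <- as.numeric(estimateLdDecay(G, markerMap(pop)))
    loci <- mergeLoci(filterSignificant(res), decay)
    lt <- if (length(loci)) lociToTable(loci) else NULL
    qt <- qtlTruth(pop); mp <- markerMap(pop)
    for (k in seq_len(nrow(qt))) {
      j <- qt$marker[k]
      if (cor(G[, j], y)^2 < 0.15) next   # only well-powered plants count
      tot <- tot + 1
      if (!is.null(lt)) {
        same <- lt[lt$chrom == mp$chrom[j], ]
        if (nrow(same) &&
            any(mp$pos[j] >= same$start - decay &
                mp$pos[j] <= same$end + decay))
          hits <- hits + 1
      }
    }
  }
  expect_gte(tot, 10)
  expect_gte(hits / tot, 0.8)
})

test_that("noiseless phenotypes rank every planted QTL near the top of the scan", {
  cfg <- simConfig(nGenotypes = 119, nSnps = 600, seed = 33, nQtl = 4,
                   qtlEffectSd = 2.5, polygenicSd = 0.5, targetH2 = 0.95)
  pop <- simulateGenotypes(cfg)
  # pin the planted effects to clearly nonzero values
  pop@qtl$effect <- c(2, -2, 2.5, -2.5)
  tg <- trueGeneticValues(simulateSpadPhenotypes(pop, cfg))
  sub <- tg[tg$env == "E1" & tg$treatment == "W" & tg$stage == "HS", ]
  y <- sub$value[match(rownames(genotypes(pop)), sub$genotype)]
  G <- genotypes(pop)
  res <- mlmScan(y, G, computeKinship(G), computeQ(G, 3), markerMap(pop))
  topN <- res$marker[order(res$p)][seq_len(3 * nrow(qtlTruth(pop)))]
  planted <- markerMap(pop)$marker[qtlTruth(pop)$marker]
  expect_true(all(planted %in% topN))
})

test_that("locus summaries conserve totals and reproduce published aggregates", {
  t6 <- table6OverlapLoci()
  s <- summarizeLoci(t6, by = "source")
  ov <- s$overall
  expect_equal(ov$n[ov$source == "total"],
               sum(ov$n[ov$source != "total"]))
  expect_equal(signif(ov$mean_p[ov$source == "measured"], 3), 6.71e-4)
  expect_equal(signif(ov$mean_p[ov$source == "predicted"], 3), 4.25e-4)
  expect_equal(round(ov$mean_r2_pct[ov$source == "measured"], 2), 10.82)
  expect_equal(round(ov$mean_r2_pct[ov$source == "predicted"], 2), 11.50)

  t5 <- table5LocusCounts()
  counts <- aggregateSiteCounts(t5)
  expect_equal(unname(counts["total"]), 308)
  expect_equal(unname(counts["predicted"]), 206)
  expect_equal(unname(counts["measured"]), 102)
  expect_equal(unname(counts["total"]),
               unname(counts["measured"] + counts["predicted"]))
})

test_that("GFF interval annotation matches a brute-force intersection oracle", {
  gffFile <- tempfile(fileext = ".gff3")
  set.seed(16)
  nGenes <- 40
  starts <- sort(sample.int(5e6, nGenes))
  ends <- starts + sample.int(5e4, nGenes)
  lines <- c("##gff-version 3",
             sprintf("1A\ttest\tgene\t%d\t%d\t.\t+\t.\tID=gene%02d",
                     starts, ends, seq_len(nGenes)))
  writeLines(lines, gffFile)
  loci <- mergeLoci(data.frame(marker = c("a", "b"), chrom = "1A",
                               pos = c(1e6, 4e6), p = c(1e-5, 1e-6),
                               markerR2 = 0.1), 1e4)
  flank <- 2e5
  ann <- annotateLoci(loci, gffFile, flank = flank)
  lt <- lociToTable(loci)
  for (i in seq_along(loci)) {
    lo <- lt$start[i] - flank; hi <- lt$end[i] + flank
    oracle <- sprintf("gene%02d", which(starts <= hi & ends >= lo))
    expect_setequal(ann[[i]], oracle)
  }
  # a gene spanning the representative marker is always reported
  spanned <- which(starts <= 1e6 & ends >= 1e6)
  if (length(spanned))
    expect_true(all(sprintf("gene%02d", spanned) %in% ann[[1]]))
})
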