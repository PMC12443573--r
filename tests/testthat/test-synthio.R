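test_that("genotype simulation is seed-deterministic and respects the MAF floor", {
  cfg <- tinyConfig(seed = 1, nSnps = 500, mafFloor = 0.05)
  p1 <- simulateGenotypes(cfg)
  p2 <- simulateGenotypes(cfg)
  expect_identical(genotypes(p1), genotypes(p2))
  expect_identical(markerMap(p1), markerMap(p2))
  expect_identical(qtlTruth(p1), qtlTruth(p2))

  p <- colMeans(genotypes(p1)) / 2
  expect_true(all(pmin(p, 1 - p) >= 0.05))
  expect_true(all(genotypes(p1) %in% 0:2))
  byChrom <- split(markerMap(p1)$pos, markerMap(p1)$chrom)
  expect_true(all(vapply(byChrom, function(x) all(diff(x) > 0), logical(1))))
})

test_that("an unstructured panel shows no dominant PCA axis", {
  cfg <- tinyConfig(seed = 2, nGenotypes = 60, nSnps = 1000, nSubpops = 1,
                    drift = 0, plotRows = 6, plotCols = 10)
  pop <- simulateGenotypes(cfg)
  G <- scale(genotypes(pop))
  v <- prcomp(G)$sdev^2
  expect_lt(v[1], 2 * mean(v))
  # and no larger than the leading axis of a column-permuted (null) matrix
  set.seed(99)
  Gp <- apply(G, 2, sample)
  vp <- prcomp(Gp)$sdev^2
  expect_lt(v[1] / mean(v), 1.25 * vp[1] / mean(vp))
})

test_that("a structured panel separates subpopulations along the top PCs", {
  cfg <- tinyConfig(seed = 3, nGenotypes = 60, nSnps = 800, nSubpops = 3,
                    drift = 0.25, plotRows = 6, plotCols = 10)
  pop <- simulateGenotypes(cfg)
  Q <- computeQ(genotypes(pop), q = 2)
  lab <- as.integer(subpopLabels(pop))
  # silhouette of the true labels in PC space
  dmat <- as.matrix(dist(Q))
  sil <- vapply(seq_len(nrow(Q)), function(i) {
    a <- mean(dmat[i, lab == lab[i] & seq_along(lab) != i])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(k) mean(dmat[i, lab == k]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

test_that("phenotype simulation hits the target heritability and is deterministic", {
  h <- vapply(1:20, function(s) {
    cfg <- simConfig(nGenotypes = 119, nSnps = 400, seed = s,
                     targetH2 = 0.7)
    pop <- simulateGenotypes(cfg)
    tr <- simulateSpadPhenotypes(pop, cfg)
    sub <- spadTable(tr)
    sub <- sub[sub$env == "E1" & sub$treatment == "W" & sub$stage == "HS", ]
    estimateHeritability(data.frame(genotype = sub$genotype,
                                    value = sub$spad))$h2
  }, numeric(1))
  expect_lt(abs(mean(h) - 0.7), 0.1)

  h0 <- vapply(1:20, function(s) {
    cfg <- simConfig(nGenotypes = 119, nSnps = 400, seed = s, nQtl = 0,
                     polygenicSd = 0, targetH2 = 0)
    pop <- simulateGenotypes(cfg)
    tr <- simulateSpadPhenotypes(pop, cfg)
    sub <- spadTable(tr)
    sub <- sub[sub$env == "E1" & sub$treatment == "W" & sub$stage == "HS", ]
    estimateHeritability(data.frame(genotype = sub$genotype,
                                    value = sub$spad))$h2
  }, numeric(1))
  expect_lte(mean(h0), 0.1)

  cfg <- tinyConfig(seed = 5)
  pop <- simulateGenotypes(cfg)
  expect_identical(spadTable(simulateSpadPhenotypes(pop, cfg)),
                   spadTable(simulateSpadPhenotypes(pop, cfg)))
})

test_that("phenotype simulation rejects inestimable settings", {
  cfg <- tinyConfig(seed = 1, targetH2 = 1)
  pop <- simulateGenotypes(tinyConfig(seed = 1))
  expect_error(simulateSpadPhenotypes(pop, cfg), "inestimable")
  cfg0 <- tinyConfig(seed = 1, nQtl = 0, polygenicSd = 0, targetH2 = 0.5)
  pop0 <- simulateGenotypes(cfg0)
  expect_error(simulateSpadPhenotypes(pop0, cfg0), "genetic variance")
})

test_that("rendered scenes honor band ordering, whiteboard DN and the SPAD link", {
  cfg <- tinyConfig(seed = 6, bandNoiseSd = 0.005)
  trial <- simulateSpadPhenotypes(simulateGenotypes(cfg), cfg)
  sc <- renderScene(trial, "E1", "W", "HS", cfg)
  pr <- extractPlotReflectance(sc)
  m <- colMeans(pr[, c("r_nir", "r_rededge", "r_green", "r_red", "r_blue")])
  expect_true(all(diff(m) < 0))           # Nir > RedEdge > Green > Red > Blue
  wb <- sc@whiteboard
  wbMean <- mean(sceneBands(sc)[["Red"]][wb[1]:wb[2], wb[3]:wb[4]])
  expect_lt(abs(wbMean - 65000) / 65000, 0.01)

  # documented monotone SPAD link: Nir reflectance rises with plot SPAD
  s <- spadTable(trial)
  sub <- s[s$env == "E1" & s$treatment == "W" & s$stage == "HS", ]
  spad <- tapply(sub$spad, sub$genotype, mean)[pr$genotype]
  expect_gt(cor(spad, sceneTruth(sc)$r_nir[match(pr$genotype,
                                                 sceneTruth(sc)$genotype)]),
            0.99)
})

test_that("noiseless scenes round-trip through zonal extraction exactly", {
  cfg <- tinyConfig(seed = 7, bandNoiseSd = 0)
  trial <- simulateSpadPhenotypes(simulateGenotypes(cfg), cfg)
  sc <- renderScene(trial, "E2", "D", "GF", cfg)
  pr <- extractPlotReflectance(sc)
  truth <- sceneTruth(sc)
  for (col in c("r_red", "r_rededge", "r_nir", "r_green", "r_blue"))
    expect_lt(max(abs(pr[[col]] - truth[[col]][match(pr$plot, truth$plot)])),
              1e-6)
  expect_error(renderScene(trial, "E1", "W", "XX", cfg), "not present")
})
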