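# Q+K mixed linear model genome scan with P3D (EMMAX-style) variance
# components, significance filtering, LD-decay locus merging, measured vs
# predicted overlap, and locus summaries.

imputeDosages <- function(G) {
  G <- as.matrix(G)
  naCount <- sum(is.na(G))
  if (naCount) {
    cm <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- cm[idx[, 2]]
    message(sprintf("mean-imputed %d missing dosages (%.2f%%)",
                    naCount, 100 * naCount / length(G)))
  }
  G
}

#' VanRaden genomic relationship matrix
#'
#' K = Z Z' / (2 sum p_j (1 - p_j)) with Z the column-centered dosage matrix
#' (centered at 2 p_j). Missing dosages are mean-imputed per marker;
#' monomorphic markers are dropped.
#'
#' @param G dosage matrix (genotypes x markers, values 0/1/2, NA allowed).
#' @return Symmetric positive semidefinite n x n matrix.
#' @export
computeKinship <- function(G) {
  G <- imputeDosages(G)
  p <- colMeans(G) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2) stopf("need >= 2 polymorphic markers for kinship")
  G <- G[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(G, 2, 2 * p)
  K <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  (K + t(K)) / 2
}

#' Population-structure covariates from PCA
#'
#' Top principal components of the centered, unit-variance scaled dosage
#' matrix, the deterministic surrogate for model-based structure estimates.
#'
#' @param G dosage matrix (genotypes x markers).
#' @param q number of components (default 3; must be < n).
#' @return n x q matrix of column-centered, mutually orthogonal scores.
#' @export
computeQ <- function(G, q = 3) {
  G <- imputeDosages(G)
  if (q >= nrow(G)) stopf("q must be < number of genotypes")
  sds <- apply(G, 2, stats::sd)
  G <- G[, sds > 0, drop = FALSE]
  pc <- stats::prcomp(G, center = TRUE, scale. = TRUE)
  Qm <- pc$x[, seq_len(q), drop = FALSE]
  colnames(Qm) <- paste0("PC", seq_len(q))
  Qm
}

# REML profile criterion for V = sigma2 * (h K + (1 - h) I) in the eigenbasis
# of K. Returns the restricted log-likelihood (up to a constant).
remlLL <- function(h, lam, yt, Xt) {
  v <- h * lam + (1 - h)
  if (any(v <= 0)) return(-Inf)
  w <- 1 / v
  XtW <- Xt * w
  XtWX <- crossprod(Xt, XtW)
  XtWy <- crossprod(XtW, yt)
  beta <- solve(XtWX, XtWy)
  res <- yt - Xt %*% beta
  rss <- sum(res^2 * w)
  np <- length(yt) - ncol(Xt)
  -0.5 * (np * log(rss / np) + sum(log(v)) +
          determinant(XtWX, logarithm = TRUE)$modulus)
}

#' Q+K mixed linear model genome scan
#'
#' Fits y = mu + Q v + x_j beta_j + u + e with u ~ (0, sigma_u^2 K) and
#' e ~ (0, sigma_e^2 I). Variance components are estimated once on the null
#' model by profiled REML over the heritability ratio in the eigenbasis of K
#' (the P3D / EMMAX approximation), then every marker is tested by
#' generalized least squares with a Wald t-test in the whitened model.
#' Marker R2 is the partial R2 of the marker in the whitened model; a raw
#' variance-fraction column is also emitted. Setting
#' \code{perMarkerREML = TRUE} re-estimates the variance components for each
#' marker (slower, exact).
#'
#' @param y phenotype vector aligned with the rows of \code{G}; individuals
#'   with missing y are removed listwise.
#' @param G dosage matrix (genotypes x markers).
#' @param K kinship matrix (NULL for the identity, reducing the scan to
#'   ordinary least squares when Q is also NULL).
#' @param Q structure covariate matrix or NULL.
#' @param map optional data.frame (marker, chrom, pos) aligned with the
#'   columns of \code{G}.
#' @param mafFloor markers below this minor-allele frequency are excluded
#'   before testing (default 0.05).
#' @param perMarkerREML exact per-marker variance components (default FALSE).
#' @return data.frame: marker, chrom, pos, effect, se, p, markerR2,
#'   markerR2raw; attribute \code{h2} holds the null-model variance ratio.
#' @export
mlmScan <- function(y, G, K = NULL, Q = NULL, map = NULL, mafFloor = 0.05,
                    perMarkerREML = FALSE) {
  G <- imputeDosages(G)
  if (length(y) != nrow(G)) stopf("y must align with the rows of G")
  keep <- is.finite(y)
  y <- y[keep]
  G <- G[keep, , drop = FALSE]
  if (!is.null(Q)) Q <- as.matrix(Q)[keep, , drop = FALSE]
  if (!is.null(K)) K <- as.matrix(K)[keep, keep, drop = FALSE]
  n <- length(y)

  if (is.null(map)) {
    mk <- colnames(G)
    if (is.null(mk)) mk <- paste0("m", seq_len(ncol(G)))
    map <- data.frame(marker = mk, chrom = NA_character_,
                      pos = NA_integer_, stringsAsFactors = FALSE)
  }
  p <- colMeans(G) / 2
  maf <- pmin(p, 1 - p)
  use <- maf >= mafFloor
  G <- G[, use, drop = FALSE]
  map <- map[use, , drop = FALSE]
  m <- ncol(G)
  if (!m) stopf("no markers pass the MAF floor")

  X <- cbind(`(Intercept)` = rep(1, n), Q)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    warnf("dropping %d collinear structure covariate(s)", length(drop))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }

  if (is.null(K)) {
    Ut <- diag(n)
    lam <- rep(1, n)
  } else {
    K <- (K + t(K)) / 2
    eg <- eigen(K, symmetric = TRUE)
    lam <- eg$values
    tol <- 1e-8 * max(abs(lam))
    if (min(lam) < -max(1e-6, 1e-4 * max(abs(lam))))
      stopf("kinship matrix is not positive semidefinite")
    lam[lam < tol] <- tol
    Ut <- t(eg$vectors)
  }
  yt <- drop(Ut %*% y)
  Xt <- Ut %*% X

  hHat <- 0
  if (!is.null(K) && stats::sd(lam) > 1e-12) {
    opt <- stats::optimize(function(h) remlLL(h, lam, yt, Xt),
                           interval = c(1e-6, 1 - 1e-6), maximum = TRUE)
    hHat <- opt$maximum
  }
  v <- hHat * lam + (1 - hHat)
  w <- 1 / sqrt(v)

  yw <- yt * w
  Xw <- Xt * w
  qrXw <- qr(Xw)
  yr <- qr.resid(qrXw, yw)
  rss0 <- sum(yr^2)

  Gt <- (Ut %*% G) * w
  Gr <- qr.resid(qrXw, Gt)
  sxx <- colSums(Gr^2)
  sxy <- drop(crossprod(Gr, yr))
  df <- n - ncol(Xw) - 1
  ok <- sxx > 1e-12
  beta <- se <- tval <- pv <- r2 <- rep(NA_real_, m)
  beta[ok] <- sxy[ok] / sxx[ok]
  rss1 <- rss0 - sxy[ok]^2 / sxx[ok]
  rss1 <- pmax(rss1, 0)
  se[ok] <- sqrt(rss1 / df / sxx[ok])
  tval[ok] <- beta[ok] / se[ok]
  pv[ok] <- 2 * stats::pt(-abs(tval[ok]), df)
  r2[ok] <- (sxy[ok]^2 / sxx[ok]) / rss0
  pv[ok & !is.finite(pv)] <- 0
  pv <- pmin(pmax(pv, .Machine$double.xmin), 1)
  pv[!ok] <- NA_real_

  if (perMarkerREML && !is.null(K)) {
    for (j in which(ok)) {
      Xj <- cbind(Xt, Ut %*% G[, j])
      opt <- stats::optimize(function(h) remlLL(h, lam, yt, Xj),
                             interval = c(1e-6, 1 - 1e-6), maximum = TRUE)
      vj <- opt$maximum * lam + (1 - opt$maximum)
      wj <- 1 / sqrt(vj)
      fit <- stats::lm.fit(Xj * wj, yt * wj)
      cf <- length(fit$coefficients)
      rssj <- sum(fit$residuals^2)
      XtXinv <- chol2inv(chol(crossprod(Xj * wj)))
      se[j] <- sqrt(rssj / fit$df.residual * XtXinv[cf, cf])
      beta[j] <- fit$coefficients[cf]
      tval[j] <- beta[j] / se[j]
      pv[j] <- 2 * stats::pt(-abs(tval[j]), fit$df.residual)
    }
  }

  varY <- stats::var(y)
  r2raw <- beta^2 * apply(G, 2, stats::var) / varY
  out <- data.frame(marker = map$marker, chrom = map$chrom, pos = map$pos,
                    effect = beta, se = se, p = pv, markerR2 = r2,
                    markerR2raw = pmin(r2raw, 1),
                    stringsAsFactors = FALSE)
  structure(out, h2 = hHat)
}

#' Filter significant associations
#'
#' Retains markers with P strictly below the threshold (default 0.001).
#'
#' @param results an \code{\link{mlmScan}} result table.
#' @param threshold significance threshold.
#' @return The significant subset (possibly empty).
#' @export
filterSignificant <- function(results, threshold = 0.001) {
  if (!nrow(results)) stopf("empty result table")
  results[!is.na(results$p) & results$p < threshold, , drop = FALSE]
}

#' Estimate the LD decay distance
#'
#' Computes pairwise r-squared against physical distance within chromosomes
#' (markers are thinned evenly when there are too many pairs), smooths
#' r-squared over distance-sorted pairs with a running mean, and reports the
#' smallest distance at which the smoothed curve falls below
#' max(0.1, background r-squared), the background being the mean r-squared
#' of inter-chromosomal marker pairs. Deterministic given the input. Falls
#' back to \code{default} (with a warning) when too few pairs are available;
#' a curve that never crosses the threshold returns the maximum observed
#' distance, flagged via the \code{crossed} attribute.
#'
#' @param G dosage matrix.
#' @param map marker map aligned with the columns of \code{G}.
#' @param maxMarkersPerChrom thinning cap per chromosome (default 150).
#' @param nBins granularity of the running-mean smoother (the window holds
#'   roughly 1/nBins of the pairs, at least 101).
#' @param default fallback decay distance, bp (default 5e6).
#' @return Decay distance in bp, with attributes \code{threshold},
#'   \code{crossed} and \code{curve}.
#' @export
estimateLdDecay <- function(G, map, maxMarkersPerChrom = 150, nBins = 25,
                            default = 5e6) {
  G <- imputeDosages(G)
  chroms <- split(seq_len(ncol(G)), map$chrom)
  dists <- r2s <- list()
  chromMeans <- numeric(0)
  for (cn in names(chroms)) {
    idx <- chroms[[cn]]
    if (length(idx) > maxMarkersPerChrom)
      idx <- idx[unique(round(seq(1, length(idx),
                                  length.out = maxMarkersPerChrom)))]
    if (length(idx) < 2) next
    sds <- apply(G[, idx, drop = FALSE], 2, stats::sd)
    idx <- idx[sds > 0]
    if (length(idx) < 2) next
    cc <- stats::cor(G[, idx, drop = FALSE])^2
    pd <- abs(outer(map$pos[idx], map$pos[idx], "-"))
    up <- upper.tri(cc)
    dists[[cn]] <- pd[up]
    r2s[[cn]] <- cc[up]
    chromMeans[cn] <- mean(colMeans(G[, idx, drop = FALSE]))
  }
  d <- unlist(dists, use.names = FALSE)
  r2 <- unlist(r2s, use.names = FALSE)
  if (length(d) < 100) {
    warnf("too few intra-chromosomal pairs (%d); returning default %g bp",
          length(d), default)
    return(structure(default, threshold = NA_real_, crossed = NA,
                     curve = NULL))
  }
  # background: mean r2 between chromosomes (independent loci)
  background <- 0
  if (length(chroms) >= 2) {
    bg <- c()
    nms <- names(chroms)[vapply(chroms, length, integer(1)) >= 1]
    for (i in seq_len(min(length(nms) - 1, 10))) {
      a <- chroms[[nms[i]]][1:min(20, length(chroms[[nms[i]]]))]
      b <- chroms[[nms[i + 1]]][1:min(20, length(chroms[[nms[i + 1]]]))]
      sa <- apply(G[, a, drop = FALSE], 2, stats::sd)
      sb <- apply(G[, b, drop = FALSE], 2, stats::sd)
      if (any(sa > 0) && any(sb > 0))
        bg <- c(bg, as.vector(stats::cor(G[, a[sa > 0], drop = FALSE],
                                         G[, b[sb > 0], drop = FALSE])^2))
    }
    if (length(bg)) background <- mean(bg)
  }
  thr <- max(0.1, background)
  # running mean of r2 over distance-sorted pairs: resolves short distances
  # at pair resolution instead of fixed-width bins
  o <- order(d)
  d <- d[o]; r2 <- r2[o]
  win <- min(length(d), max(101, 2 * floor(length(d) / (2 * nBins)) + 1))
  if (win %% 2 == 0) win <- win + 1
  sm <- as.numeric(stats::filter(r2, rep(1 / win, win), sides = 2))
  ok <- !is.na(sm)
  curve <- data.frame(dist = d[ok], r2 = r2[ok], smoothed = sm[ok])
  below <- which(curve$smoothed < thr)
  if (length(below)) {
    structure(curve$dist[below[1]], threshold = thr, crossed = TRUE,
              curve = curve)
  } else {
    structure(max(d), threshold = thr, crossed = FALSE, curve = curve)
  }
}

#' Merge significant markers into loci
#'
#' Single-linkage chaining per chromosome: a significant marker joins a
#' cluster when it lies within the decay distance of any member. The
#' representative is the member with the smallest P (ties broken by smaller
#' bp). Merging the representatives of merged loci is a no-op (idempotence).
#'
#' @param significant a table of significant markers (columns marker, chrom,
#'   pos, p, markerR2; optional source/env/treatment/stage columns are
#'   carried through).
#' @param decayDistance merge window, bp (> 0).
#' @return A \link[GenomicRanges]{GRanges} with one range per locus spanning
#'   its member markers; metadata columns nMarkers, members, repMarker,
#'   repPos, repP, minR2, maxR2 plus any carried key columns.
#' @export
mergeLoci <- function(significant, decayDistance) {
  if (decayDistance <= 0) stopf("decayDistance must be > 0")
  carry <- intersect(c("source", "env", "treatment", "stage"),
                     names(significant))
  if (!nrow(significant)) {
    gr <- GenomicRanges::GRanges()
    mc <- S4Vectors::DataFrame(nMarkers = integer(0),
                               members = IRanges::CharacterList(),
                               repMarker = character(0),
                               repPos = integer(0), repP = numeric(0),
                               minR2 = numeric(0), maxR2 = numeric(0))
    for (cl in carry) mc[[cl]] <- character(0)
    S4Vectors::mcols(gr) <- mc
    return(gr)
  }
  rows <- list()
  for (cn in unique(significant$chrom)) {
    sub <- significant[significant$chrom == cn, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    gaps <- diff(sub$pos)
    cluster <- cumsum(c(1, gaps > decayDistance))
    for (cl in unique(cluster)) {
      mem <- sub[cluster == cl, , drop = FALSE]
      rep <- mem[order(mem$p, mem$pos), , drop = FALSE][1, ]
      row <- data.frame(chrom = cn, start = min(mem$pos),
                        end = max(mem$pos), nMarkers = nrow(mem),
                        repMarker = rep$marker, repPos = rep$pos,
                        repP = rep$p,
                        minR2 = min(mem$markerR2),
                        maxR2 = max(mem$markerR2),
                        stringsAsFactors = FALSE)
      for (cc in carry) row[[cc]] <- mem[[cc]][1]
      row$members <- I(list(mem$marker))
      rows[[length(rows) + 1]] <- row
    }
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end))
  mc <- S4Vectors::DataFrame(nMarkers = tab$nMarkers,
                             members = S4Vectors::List(tab$members),
                             repMarker = tab$repMarker, repPos = tab$repPos,
                             repP = tab$repP, minR2 = tab$minR2,
                             maxR2 = tab$maxR2)
  for (cc in carry) mc[[cc]] <- tab[[cc]]
  S4Vectors::mcols(gr) <- mc
  gr
}

#' Pair measured and predicted loci
#'
#' A pair is emitted when two loci share a chromosome and their
#' representative positions differ by at most \code{window}; pairing is
#' greedy by distance and each locus joins at most one pair.
#'
#' @param measured,predicted locus \code{GRanges} from
#'   \code{\link{mergeLoci}}.
#' @param window pairing window, bp (typically the LD decay distance).
#' @return data.frame: chrom, measuredMarker, measuredPos, predictedMarker,
#'   predictedPos, distance.
#' @export
overlapLoci <- function(measured, predicted, window) {
  if (window <= 0) stopf("window must be > 0")
  empty <- data.frame(chrom = character(0), measuredMarker = character(0),
                      measuredPos = integer(0),
                      predictedMarker = character(0),
                      predictedPos = integer(0), distance = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(measured) || !length(predicted)) return(empty)
  md <- data.frame(chrom = as.character(GenomicRanges::seqnames(measured)),
                   marker = S4Vectors::mcols(measured)$repMarker,
                   pos = S4Vectors::mcols(measured)$repPos)
  pd <- data.frame(chrom = as.character(GenomicRanges::seqnames(predicted)),
                   marker = S4Vectors::mcols(predicted)$repMarker,
                   pos = S4Vectors::mcols(predicted)$repPos)
  cand <- list()
  for (i in seq_len(nrow(md))) for (j in seq_len(nrow(pd))) {
    if (md$chrom[i] == pd$chrom[j] &&
        abs(md$pos[i] - pd$pos[j]) <= window)
      cand[[length(cand) + 1]] <- c(i, j, abs(md$pos[i] - pd$pos[j]))
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
  out <- list()
  takenM <- rep(FALSE, nrow(md)); takenP <- rep(FALSE, nrow(pd))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (takenM[i] || takenP[j]) next
    takenM[i] <- takenP[j] <- TRUE
    out[[length(out) + 1]] <- data.frame(
      chrom = md$chrom[i], measuredMarker = md$marker[i],
      measuredPos = md$pos[i], predictedMarker = pd$marker[j],
      predictedPos = pd$pos[j], distance = cand[k, 3],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Convert locus GRanges to a flat table
#'
#' @param loci a locus \code{GRanges} from \code{\link{mergeLoci}}.
#' @return data.frame with one row per locus (p = representative P,
#'   marker_r2_pct = max member marker R2 in percent).
#' @export
lociToTable <- function(loci) {
  mc <- as.data.frame(S4Vectors::mcols(loci))
  mc$members <- NULL
  data.frame(chrom = as.character(GenomicRanges::seqnames(loci)),
             start = GenomicRanges::start(loci),
             end = GenomicRanges::end(loci),
             marker = mc$repMarker, pos = mc$repPos, p = mc$repP,
             marker_r2_pct = 100 * mc$maxR2, nMarkers = mc$nMarkers,
             mc[, setdiff(names(mc),
                          c("repMarker", "repPos", "repP", "minR2",
                            "maxR2", "nMarkers")), drop = FALSE],
             stringsAsFactors = FALSE)
}

#' Summarize loci per cell and overall
#'
#' From a flat locus table (one row per locus with columns p and
#' marker_r2_pct plus grouping keys), computes per-cell counts, minimum P
#' and marker-R2 ranges, and overall totals with arithmetic mean P and mean
#' marker R2 per source. Totals always equal the sum of their cells.
#'
#' @param locusTable data.frame, e.g. from \code{\link{lociToTable}} or
#'   \code{\link{table6OverlapLoci}}.
#' @param by grouping columns present in the table (defaults to whichever
#'   of treatment, stage, source exist).
#' @return list(cells, overall): \code{cells} has one row per group with
#'   n, min_p, mean_p, r2_min_pct, r2_max_pct; \code{overall} has one row
#'   per source plus a "total" row with n, mean_p, mean_r2_pct.
#' @export
summarizeLoci <- function(locusTable,
                          by = intersect(c("treatment", "stage", "source"),
                                         names(locusTable))) {
  if (!all(c("p", "marker_r2_pct") %in% names(locusTable)))
    stopf("locusTable needs columns p and marker_r2_pct")
  cells <- NULL
  if (length(by)) {
    grp <- interaction(locusTable[by], drop = TRUE, sep = "\r")
    cells <- do.call(rbind, lapply(levels(grp), function(g) {
      sub <- locusTable[grp == g, ]
      keys <- sub[1, by, drop = FALSE]
      cbind(keys, data.frame(n = nrow(sub), min_p = min(sub$p),
                             mean_p = mean(sub$p),
                             r2_min_pct = min(sub$marker_r2_pct),
                             r2_max_pct = max(sub$marker_r2_pct)),
            row.names = NULL)
    }))
  }
  srcCol <- if ("source" %in% names(locusTable)) locusTable$source
            else rep("all", nrow(locusTable))
  overall <- do.call(rbind, lapply(unique(srcCol), function(s) {
    sub <- locusTable[srcCol == s, ]
    data.frame(source = s, n = nrow(sub), mean_p = mean(sub$p),
               mean_r2_pct = mean(sub$marker_r2_pct),
               stringsAsFactors = FALSE)
  }))
  overall <- rbind(overall,
                   data.frame(source = "total", n = nrow(locusTable),
                              mean_p = mean(locusTable$p),
                              mean_r2_pct = mean(locusTable$marker_r2_pct),
                              stringsAsFactors = FALSE))
  list(cells = cells, overall = overall)
}

#' Aggregate published per-cell site counts
#'
#' Sums locus counts by source and overall from a per-cell count table (see
#' \code{\link{table5LocusCounts}}).
#'
#' @param cellCounts data.frame with columns source and site_number.
#' @return Named numeric vector: one entry per source plus "total".
#' @export
aggregateSiteCounts <- function(cellCounts) {
  per <- tapply(cellCounts$site_number, cellCounts$source, sum)
  c(as.list(per), total = sum(cellCounts$site_number)) |> unlist()
}

#' Annotate loci with overlapping gene models
#'
#' Reports gene models whose span intersects each locus interval extended by
#' \code{flank} on both sides. Coordinates are 1-based inclusive; malformed
#' GFF lines are skipped by the importer.
#'
#' @param loci locus \code{GRanges}.
#' @param gff path to a GFF3 file, or a \code{GRanges} of gene models.
#' @param flank extension in bp (default 0).
#' @param idColumn metadata column holding gene identifiers (default "ID",
#'   falling back to "Name").
#' @return A \code{CharacterList} of gene identifiers, one element per
#'   locus.
#' @export
annotateLoci <- function(loci, gff, flank = 0, idColumn = "ID") {
  genes <- if (is(gff, "GRanges")) gff else rtracklayer::import(gff)
  if ("type" %in% names(S4Vectors::mcols(genes)) &&
      any(S4Vectors::mcols(genes)$type == "gene"))
    genes <- genes[S4Vectors::mcols(genes)$type == "gene"]
  ids <- S4Vectors::mcols(genes)[[idColumn]]
  if (is.null(ids)) ids <- S4Vectors::mcols(genes)[["Name"]]
  if (is.null(ids)) ids <- paste0("gene_", seq_along(genes))
  ext <- GenomicRanges::resize(loci,
                               GenomicRanges::width(loci) + 2 * flank,
                               fix = "center")
  hits <- GenomicRanges::findOverlaps(ext, genes, ignore.strand = TRUE)
  out <- S4Vectors::splitAsList(ids[S4Vectors::subjectHits(hits)],
                                factor(S4Vectors::queryHits(hits),
                                       levels = seq_along(loci)))
  names(out) <- S4Vectors::mcols(loci)$repMarker
  out
}
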