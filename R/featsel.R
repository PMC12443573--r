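# Vegetation-index ranking (random-forest importance + Pearson correlation
# with SPAD) and selection of the inversion-model feature subset.

#' Random-forest importance of vegetation indices for SPAD
#'
#' Fits a seeded regression random forest of SPAD on the index columns and
#' returns impurity-based importances normalized to sum to 1.
#'
#' @param vi numeric data.frame/matrix of vegetation-index columns (one row
#'   per plot); non-index key columns are dropped automatically.
#' @param spad numeric SPAD vector aligned with the rows of \code{vi}.
#' @param nTrees number of trees (default 500).
#' @param seed RNG seed.
#' @return Named numeric vector of importances (sum 1).
#' @export
rfImportance <- function(vi, spad, nTrees = 500, seed = 1) {
  x <- asIndexMatrix(vi)
  if (nrow(x) != length(spad)) stopf("vi and spad lengths differ")
  keep <- stats::complete.cases(x) & is.finite(spad)
  x <- x[keep, , drop = FALSE]
  spad <- spad[keep]
  if (nrow(x) < 20) stopf("need >= 20 paired observations, got %d", nrow(x))
  if (stats::sd(spad) == 0)
    stopf("SPAD vector is constant; no variance to explain")
  withSeed(seed, {
    rf <- randomForest::randomForest(x, spad, ntree = nTrees)
    imp <- drop(randomForest::importance(rf, type = 2))
  })
  imp <- pmax(imp, 0)
  imp / sum(imp)
}

asIndexMatrix <- function(vi) {
  vi <- as.data.frame(vi)
  cols <- intersect(viNames(), names(vi))
  if (!length(cols)) cols <- names(vi)[vapply(vi, is.numeric, logical(1))]
  as.matrix(vi[, cols, drop = FALSE])
}

#' Pearson correlation of each index with SPAD
#'
#' Pairwise-complete Pearson correlation per index; indices with fewer than
#' three valid pairs are flagged missing (\code{NA}).
#'
#' @inheritParams rfImportance
#' @return Named numeric vector of correlations in [-1, 1] (or NA).
#' @export
correlateWithSpad <- function(vi, spad) {
  x <- asIndexMatrix(vi)
  if (nrow(x) != length(spad)) stopf("vi and spad lengths differ")
  vapply(colnames(x), function(nm) {
    ok <- is.finite(x[, nm]) & is.finite(spad)
    if (sum(ok) < 3) return(NA_real_)
    if (stats::sd(x[ok, nm]) == 0 || stats::sd(spad[ok]) == 0)
      return(NA_real_)
    stats::cor(x[ok, nm], spad[ok])
  }, numeric(1))
}

#' Select the inversion-model index subset
#'
#' The selection rule is the union of the top-\code{kTop} indices by
#' random-forest importance and the index with the largest absolute Pearson
#' correlation; ordered by descending importance with the correlation pick
#' appended if not already present. Ties are broken by alphabetical index
#' name.
#'
#' @param importance named importance vector (see \code{\link{rfImportance}}).
#' @param r named correlation vector (see \code{\link{correlateWithSpad}}).
#' @param kTop how many top-importance indices to keep (default 5).
#' @return Character vector of selected index names, with attribute
#'   \code{provenance} ("importance-rank" / "correlation-max" per pick).
#' @export
selectIndices <- function(importance, r, kTop = 5) {
  if (any(is.na(importance))) stopf("importance table incomplete")
  nms <- names(importance)
  ord <- nms[order(-importance, nms)]
  top <- ord[seq_len(min(kTop, length(ord)))]
  rOk <- r[!is.na(r)]
  sel <- top
  prov <- rep("importance-rank", length(top))
  if (length(rOk)) {
    cand <- names(rOk)[order(-abs(rOk), names(rOk))][1]
    if (!cand %in% sel) {
      sel <- c(sel, cand)
      prov <- c(prov, "correlation-max")
    } else prov[match(cand, sel)] <- "importance-rank+correlation-max"
  }
  structure(sel, provenance = prov)
}
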