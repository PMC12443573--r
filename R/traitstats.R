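# Descriptive phenotype statistics and ANOVA broad-sense heritability.

#' Summarize a replicated trait
#'
#' Statistics are computed over genotype means (replicates averaged first,
#' the unit entering the genome scan): mean, median, CV (percent), sample
#' standard deviation, broad-sense heritability (when >= 2 replicates per
#' genotype are available), max, min and n. Set \code{perReplicate = TRUE}
#' to summarize the raw replicate values instead.
#'
#' @param values data.frame with columns genotype, value and optionally
#'   replicate.
#' @param perReplicate summarize raw replicate values rather than genotype
#'   means.
#' @return One-row data.frame: mean, median, cv_pct, sd, h2, max, min, n.
#' @export
summarizeTrait <- function(values, perReplicate = FALSE) {
  values <- values[is.finite(values$value), ]
  if (!nrow(values)) stopf("all values missing in this cell")
  if (length(unique(values$genotype)) < 2) stopf("need >= 2 genotypes")
  v <- if (perReplicate) values$value
       else as.numeric(tapply(values$value, values$genotype, mean))
  h2 <- NA_real_
  nRep <- tapply(values$value, values$genotype, length)
  if (min(nRep) >= 2)
    h2 <- estimateHeritability(values)$h2
  data.frame(mean = mean(v), median = stats::median(v),
             cv_pct = if (mean(v) > 0) 100 * stats::sd(v) / mean(v)
                      else NA_real_,
             sd = stats::sd(v), h2 = h2, max = max(v), min = min(v),
             n = length(v))
}

#' Broad-sense heritability from replicated genotype values
#'
#' One-way ANOVA estimator: the residual (within-genotype) mean square
#' estimates the environmental variance, the genetic variance is
#' (MS_between - MS_within) / r truncated at zero (r = replicate count, the
#' unbalanced-design effective value when replicate numbers differ), and
#' h2 = sigma_g2 / (sigma_g2 + sigma_e2), defined as 0 when both components
#' vanish.
#'
#' @param values data.frame with columns genotype and value; every genotype
#'   needs >= 2 replicates.
#' @return list(sigmaG2, sigmaE2, r, h2).
#' @export
estimateHeritability <- function(values) {
  values <- values[is.finite(values$value), ]
  g <- factor(values$genotype)
  nRep <- tabulate(g)
  if (any(nRep < 2))
    stopf("heritability inestimable: genotype(s) with a single replicate")
  fit <- stats::lm(value ~ g, data = data.frame(value = values$value, g = g))
  a <- suppressWarnings(stats::anova(fit))  # only mean squares are used
  msB <- a$`Mean Sq`[1]
  msW <- a$`Mean Sq`[2]
  nTot <- length(values$value)
  k <- nlevels(g)
  r <- (nTot - sum(nRep^2) / nTot) / (k - 1)   # effective replicate count
  sigmaE2 <- msW
  sigmaG2 <- max(0, (msB - msW) / r)
  h2 <- if (sigmaG2 + sigmaE2 == 0) 0 else sigmaG2 / (sigmaG2 + sigmaE2)
  list(sigmaG2 = sigmaG2, sigmaE2 = sigmaE2, r = r, h2 = h2)
}

#' Trait summary over all trial cells
#'
#' Applies \code{\link{summarizeTrait}} to every (env, treatment, stage)
#' cell of a long trait table for one or more sources.
#'
#' @param traits data.frame with columns genotype, env, treatment, stage,
#'   replicate, value, source.
#' @return data.frame with one row per (env, treatment, stage, source).
#' @export
summarizeTraitTable <- function(traits) {
  cells <- unique(traits[, c("env", "treatment", "stage", "source")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- traits[traits$env == cells$env[i] &
                  traits$treatment == cells$treatment[i] &
                  traits$stage == cells$stage[i] &
                  traits$source == cells$source[i], ]
    cbind(cells[i, ], summarizeTrait(sub), row.names = NULL)
  })
  do.call(rbind, rows)
}
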