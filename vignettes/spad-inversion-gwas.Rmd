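---
title: "From five-band plot imagery to chlorophyll loci: methods and design choices"
author: "spadGWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From five-band plot imagery to chlorophyll loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spadGWAS)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the parameters that matter, and the places
where the design was genuinely open and a choice had to be made. It states
no empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## The measurement chain

### Radiometric calibration

Raw multispectral pixels are digital numbers (DN). Calibration is
single-point against a reference whiteboard that reads DN 65000 at 99.8 %
reflectivity:

$$\rho = \mathrm{DN} \times 0.998 / 65000.$$

The model is linear through the origin — no dark-current or second
reference panel term, because the measurement protocol being modeled uses
only the whiteboard. Negative DN is rejected as a data error rather than
clipped.

### Zonal statistics

Per-plot reflectance is the arithmetic mean of calibrated DN over the
pixels whose centers fall inside the plot rectangle. One convention is used
everywhere and documented once: raster indices are 1-based inclusive ranges
in R (0-based in files written to disk), genetic coordinates are 1-based
bp. A plot with zero pixels is an error naming the plot, never a silent
`NaN`. Downstream summaries average *plot-level* means, not pixels, because
the cultivar (its plot) is the experimental unit.

### Vegetation indices

All 18 indices are computed exactly as printed in the source formula table,
including two deliberate departures from the wider literature:

* **VARIred** keeps its printed 1.7/0.7/2.3/1.3 coefficients even though
  common literature forms differ — the goal is to reproduce this analysis,
  not the literature.
* **CARI** is printed as `(RRed_edge−RRed)/0.2*(RRed_edge+RRed)`, which is
  precedence-ambiguous. The default reading divides by
  $0.2\,(R_{RE}+R_{Red})$, which is bounded and behaves like the other
  normalized-ratio features; the literal left-to-right reading is available
  via `computeVI(..., cariMode = "literal")`. Nothing in the source states
  which the authors computed.

A zero denominator yields a flagged missing value (`NA` plus a validity
flag), never a silent zero, and invalid values are excluded pairwise from
correlations. The whole set is verified against an independent
direct-transcription oracle to 1e-12 on 1000 random band vectors.

## Feature selection

The analysis being reproduced combines "top five importance" statements
with correlation-heatmap maxima but never states a formal rule. The package
makes the implicit rule explicit and testable: select the union of the
top-`kTop` (default 5) indices by seeded random-forest impurity importance
(500 trees, unlimited depth — conventional defaults, recorded in the
output) and the single index with the largest |Pearson r|. Ties break
alphabetically and are deterministic. The heatmap values labeled R² in the
source are signed, so they are treated as Pearson r (a negative R² is
impossible). Selection is computed per (environment, treatment, stage)
cell; pooling treatments within an environment — which the source is
ambiguous about — is achieved by passing pooled tables to the same
functions.

## The inversion model

The SPAD inversion network is the literal backpropagation algorithm: one
hidden layer of 18 units, tanh activation (the source names the
sigmoid/tanh family; tanh suits zero-centered standardized inputs), linear
output, full-batch gradient descent on mean squared error at learning rate
0.001 for 50 epochs (all configurable). Weights are initialized from a
seeded scaled-uniform distribution, so a fixed seed reproduces weights
bit-for-bit. Features *and* target are standardized by training-split
statistics only, which prevents validation leakage (the source is silent on
this point).

Numerical choices:

* A non-finite loss aborts with the offending epoch (divergence is an
  error, not a warning).
* A zero-variance (constant) target makes the standardization degenerate;
  the exact MSE optimum — all outputs at the target value — is returned in
  closed form rather than approached asymptotically by gradient descent.
* Fitting quality is reported over eight independent random 70/30
  re-splits (84 train / 35 validation at n = 119). The source's "eight
  iterations" could also mean eight restarts of one split; both modes are
  implemented (`replicateFit(..., mode = "restart")`), re-splitting is the
  default.

Metrics: r is Pearson correlation and R² is reported as r², because the
source's own (r, R²) pairs satisfy that identity; the
coefficient-of-determination form is emitted as a secondary column, as is
RMSE on the standardized scale (the source's RMSE magnitudes of 0.14–0.28
are far below raw SPAD scale, suggesting standardized reporting — both are
given). RE is mean absolute relative error, the most common reading
consistent with the reported magnitudes (0.02–0.04).

The network's MSE objective pulls predictions toward the conditional mean,
so predicted trait tables are systematically less dispersed than measured
ones (smaller CV, shrunken extremes). The tests assert this as a frequency
property over seeds, not as exact values.

## Trait statistics and heritability

Summaries (mean, median, CV = 100 σ/μ, σ, extremes) are computed over
genotype means with replicates averaged first — the unit that enters the
genome scan; a per-replicate mode exists. Broad-sense heritability uses the
one-way ANOVA estimator:

$$\hat\sigma^2_e = MS_W,\qquad
  \hat\sigma^2_g = \max\!\left(0, \frac{MS_B - MS_W}{r}\right),\qquad
  h^2_B = \frac{\hat\sigma^2_g}{\hat\sigma^2_g + \hat\sigma^2_e},$$

with $r$ the replicate count (the standard effective value for unbalanced
designs). Negative genetic-variance estimates are truncated at zero, the
usual ANOVA-method fix that keeps $h^2_B \in [0,1]$; $0/0$ is defined as 0.
The source does not say which decomposition it used; ANOVA is the simplest
estimator consistent with a two-replicate design and is cross-checked
against brute-force sums of squares. REML-based and multi-environment
(G×E) decompositions are out of scope.

## The genome scan

The association model is the Q+K mixed linear model

$$y = \mu + Qv + x_j\beta_j + u + e,\qquad
  u \sim (0, \sigma^2_u K),\; e \sim (0, \sigma^2_e I),$$

with these concrete choices:

* **K** is the VanRaden centered relationship matrix
  $ZZ^\top / 2\sum_j p_j(1-p_j)$. Missing dosages are mean-imputed per
  marker (rate logged); markers below MAF 0.05 are excluded before
  testing.
* **Q** is the top-3 principal components of the scaled dosage matrix — a
  deterministic, dependency-free surrogate for model-based structure
  estimates, matching the three subgroups of the emulated panel. Collinear
  columns are dropped with a warning.
* **Variance components** are estimated once on the null model by profiled
  REML over the ratio $h = \sigma^2_u/(\sigma^2_u+\sigma^2_e)$ in the
  eigenbasis of K (the P3D/EMMAX approximation), then every marker is
  tested by whitened least squares with a Wald t-test. Exact per-marker
  REML is available behind `perMarkerREML = TRUE`. With K = I and no Q the
  scan reduces *exactly* to the ordinary per-marker regression t-test,
  which the tests verify to 1e-8.
* **Marker R²** is not defined in the source; it is implemented as the
  partial R² of the marker in the whitened model, with a raw
  variance-fraction column emitted alongside.
* The significance rule is **strictly** P < 0.001, honoring the printed
  inequality: a marker at exactly 0.001 is excluded.

### LD decay and locus merging

The merge window is the LD decay distance: pairwise $r^2$ against physical
distance within chromosomes (markers thinned evenly when pairs are too
many — thinning is deterministic, so the estimate is reproducible), a
running mean over distance-sorted pairs, and the smallest distance where
the smoothed curve falls below max(0.1, background), the background being
the mean inter-chromosomal $r^2$. A curve that never crosses (perfect LD)
returns the maximum observed distance, flagged; too few pairs falls back
to a configured default (5 Mb) with a warning.

Significant markers are merged per chromosome by single-linkage chaining —
a marker joins a cluster when it is within the decay distance of any
member, which in one dimension is chaining consecutive gaps. The
representative is the member with minimum P, ties broken by smaller bp.
Merging is idempotent. Measured and predicted loci are paired greedily by
representative distance on the same chromosome within a window (default
the decay distance), each locus in at most one pair. Wheat chromosome
labels (1A…7D) are opaque strings ordered by (number, letter).

Gene annotation is a local interval lookup against a user-supplied GFF3
(1-based inclusive, optional flank), replacing the source's online BLAST
workflow; no attempt is made to reproduce its specific candidate-gene
table, several entries of which are garbled in the source text.

## The synthetic trial

The generator exists so that every stage of the pipeline is testable
without the unpublished field data. What it emulates, and how:

* **Panel and markers.** 119 genotypes in 3 subpopulations on 21
  chromosomes. Allele frequencies follow a Balding–Nichols model (default
  drift F = 0.15), which produces exactly the Q/K-correctable confounding
  that motivates the mixed model. MAF-filtered markers get sorted uniform
  positions; there is no within-chromosome LD by default (planted LD
  blocks are constructed explicitly in the tests that need them).
* **Phenotypes.** SPAD = stage/treatment/environment baseline + planted
  QTL effects + polygenic term + i.i.d. replicate noise, two replicates
  per cell as in the emulated design. Baselines rise from heading to grain
  filling within 54–58 SPAD; the replicate noise variance is set from the
  realized genetic variance so the expected ANOVA heritability equals
  `targetH2` (default 0.70). Default effect scales (`qtlEffectSd` 0.8,
  `polygenicSd` 1.8 SPAD units) put the realized genotype-mean CV in the
  3–7 % range of the emulated trial. `targetH2 = 1` is rejected as
  inestimable under replicate noise.
* **Scenes.** Rectangular plots on a grid with a reserved whiteboard
  rectangle rendered at reflectance 0.998. Per-plot band reflectance is an
  affine function of the plot's replicate-mean SPAD around the published
  per-treatment, per-stage band means: visible bands decrease with SPAD
  (chlorophyll absorbs), near-infrared increases, at per-sd slopes of
  −0.006…−0.020 and +0.020 reflectance units. The source never states how
  plant-level SPAD maps to plot spectra, so this functional form is a free
  modeling choice — the simplest one that gives the index–SPAD
  correlations the downstream stages need. Per-pixel Gaussian noise (sd
  0.01 reflectance) is added; values outside [0, 1] are clipped with a
  logged count. DN = ρ × 65000 / 0.998, written as 16-bit multiband TIFF.

Everything is seeded: a fixed `SimConfig` seed reproduces genotypes,
trials, scenes and the whole pipeline (including output file hashes)
bit-for-bit.

**What passing tests do and do not show.** The synthetic data share the
design, magnitudes, heritability and confounding structure of the emulated
trial, so the tests demonstrate that the *algorithms* are correct and
calibrated (type-I error at the scan threshold, heritability recovery,
planted-QTL recovery, shrinkage of network predictions). They do not show
that real wheat canopies satisfy the affine SPAD–reflectance link, nor do
they reproduce the source's field correlations or its specific loci — the
underlying data are unpublished. The desk-recomputable published numbers
(band-decline percentages, locus counts and overlap-locus aggregates) are
instead recomputed exactly from shipped plain-text transcriptions of the
printed tables; a few printed percent-decreases disagree with their own
table's cells at the last digit (unrounded internal data, presumably), and
only the arithmetic-consistent cells are asserted.

## Problem sizes used in the checks

The acceptance checks run the complete pipeline at the study's own scale —
119 genotypes, 2000 markers, all 12 environment × treatment × stage cells,
both trait sources — and finish in well under a minute on one CPU; the
statistical calibration suites use 25 structured-null scans of 2000
markers (≥ 50 000 marker tests) for the type-I error rate, 20 seeds for
heritability and locus-recovery frequencies, and 10 seeds for the
shrinkage property. These sizes were chosen as the smallest that make the
frequency assertions statistically meaningful.

## Known limitations

* The scene model has no soil/shadow classes, BRDF or sun-angle effects,
  and plots are axis-aligned rectangles; orthomosaic stitching and
  georeferencing are out of scope.
* The genome scan is single-marker, additive-dosage; no multi-locus
  models, no epistasis, no imputation beyond marker means.
* Predicted traits carry no replicate structure (one network prediction
  per genotype and cell), so heritability is reported for measured traits
  only.
* The LD-decay estimator assumes physical distance is the only driver of
  within-chromosome correlation; in default synthetic panels (no LD) it
  returns the short-distance noise floor, which is then simply a
  conservative merge window.
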