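---
title: "Classifying anticancer peptides with composition features and a voting ensemble"
author: "pepVote"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying anticancer peptides with composition features and a voting ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepVote)
```

## The problem

Anticancer peptides (ACPs) are short sequences — typically 10–50 residues,
often cationic and amphipathic, which helps them engage anionic tumour cell
membranes — that are screened computationally before synthesis. pepVote
implements a sequence-only binary classifier for the ACP / non-ACP (NACP)
decision: fixed-length composition features, identity-based redundancy
filtering, principal-component pruning, and a weighted-voting ensemble of
three standard learners, evaluated with the five metrics conventional in
this literature.

## The model

### Feature encoders

Each peptide `P = R1..RL` over the 20-letter alphabet is mapped to
probability vectors:

* **AAC** (20 components): residue frequencies `n_j / L`.
* **DPC** (400): adjacent ordered-pair frequencies over `L - 1` windows.
* **TPC** (8000): ordered-triple frequencies from a width-3 sliding
  window, divided by `L - 2`.
* **IPseAAC** (`20 + lambda`): the 20 residue frequencies `f_u` plus
  `lambda` sequence-order correlation factors
  `theta_n = mean_k I(R_k, R_{k+n})`, where `I(i, j)` is the mean squared
  difference of nine standardized physicochemical scale values between the
  two residues. The joint normalization
  `x_u = f_u / (sum f + w sum theta)` and
  `x_{20+j} = w theta_j / (sum f + w sum theta)` makes the vector sum
  to 1. Defaults: `lambda = 1` (the setting that performs best in
  published ablations of this model family), `w = 0.05` (the canonical
  pseudo-composition weight).

Fusion is plain concatenation with encoder-prefixed column names; all four
encoders at `lambda = 1` give 8441 columns. Column order is fixed
lexicographic so serialized matrices are stable across runs.

Two readings exist for the correlation tiers: pairing residues `n` apart
(`tier_mode = "canonical"`, the default, matching standard
pseudo-amino-acid practice) or keeping adjacent pairs at every tier and
only shortening the averaging window (`"literal"`). The literal form makes
all tiers nearly identical, which is why canonical is the default; both are
implemented and tested.

### The property table

The nine scales — hydrophobicity, hydrophilicity, charge, flexibility,
irreplaceability, solvent-accessible surface area, polarity, polarizability
and rigidity — are not fixed by any single canonical source, so the package
ships a versioned table (`inst/extdata/aa_properties.tsv`) of standard
literature scales: Kyte–Doolittle, Hopp–Woods, net side-chain charge at
pH 7 (His counted +0.1), Bhaskaran–Ponnuswamy flexibility, inverse Dayhoff
relative mutability as an irreplaceability measure, Tien et al. maximal
ASA, Grantham polarity, Charton–Charton polarizability, and Zimmerman
bulkiness as a steric rigidity proxy. Every scale is standardized to mean 0
and population SD 1 across the 20 residues, which makes `I(.,.)`
scale-free; any monotone-equivalent replacement table can be supplied via
`loadPropertyTable()`. Because the scales enter only through standardized
differences, conclusions from the structural tests do not depend on the
exact literature values chosen.

### Redundancy filtering

Near-duplicate peptides inflate apparent accuracy. The package applies the
greedy incremental clustering strategy of identity-reduction tools:
records are visited longest-first (ties by id) and discarded when their
identity to an existing, no-shorter representative *strictly exceeds* the
threshold (default 0.90, i.e. "more than 90 % identical"). Identity is the
maximal match count over global alignments with match 1, mismatch 0, gap 0
— equivalently the longest-common-subsequence length — divided by the
shorter length, the convention those tools use for peptides. The DP kernel
is in C++; a residue-composition upper bound (shared counts cap the match
count) skips pairs that cannot reach the threshold, the same idea as word
filtering in the original tools. Million-scale k-mer prefiltering is out of
scope.

### PCA pruning

Feature pruning is the eigendecomposition of the sample covariance matrix
(divisor `Q - 1`; the divisor keeps eigenvalues unbiased) of the centered
*training* matrix only — test rows are projected with training means, so no
information leaks across the split. The retained dimension `K` is the
smallest prefix reaching 95 % cumulative explained variance by default
(a standard, reportable criterion), overridable by an explicit `K`, and
always capped below the number
of training rows. Implementation uses the singular value decomposition
(`prcomp`), which avoids forming the 8441 × 8441 covariance matrix; tests
verify the eigen-equation `C v = lambda v` and agreement with a brute-force
`eigen(cov(x))` on small instances. Eigenvector signs are fixed by making
each component's largest-magnitude loading positive so fitted models are
reproducible. PCA's sensitivity to outliers is documented, not mitigated —
robust variants are out of scope.

### Classifiers and voting

* **SVM**: radial-basis kernel `exp(-gamma ||xi - xj||^2)`; `C` and
  `gamma` chosen by seeded 5-fold cross-validated accuracy over the
  canonical grid `C in 2^{-5,-3,..,15}`, `gamma in 2^{-15,..,3}`
  (overridable). Ties go to the smaller `C`, then smaller
  `gamma`, so selection is deterministic.
* **RF**: 100 bootstrap-bagged trees with random feature subsetting;
  the tree count is the one conventional in this protocol and is
  configurable.
* **NB**: Gaussian class-conditional naive Bayes with per-class feature
  means and variances; variances are floored at 1e-9 so constant features
  cancel from the posterior ratio.
* **KNN** (Euclidean, odd `k`, distance ties to the lower training-row
  index) is provided for ablations but is not part of the default
  ensemble, mirroring its absence from the combined model.

The ensemble sums, per class, the weights of the bases voting for it and
takes the argmax. "Best weights" are operationalized two ways: `equal`
(default — reproducible and assumption-free) and `cv_accuracy`
(proportional to each base's cross-validated training accuracy). Exact
weight ties fall to the SVM's vote by default (the strongest individual
learner), or to the training majority class. Class weighting for the
imbalanced 1:10 setting is deliberately off by default; rebalancing is a
modelling choice a user must opt into.

### Evaluation

With ACP positive: accuracy, sensitivity, specificity, F1 and MCC from the
confusion matrix, in their standard confusion-matrix definitions. A ratio with a zero denominator is reported as `NA` with a
recorded reason, never silently 0. The train/test split is 70/30 with the
training count rounded half-to-even — the unique common convention
reproducing the canonical benchmark splits (344 → 241/103,
2475 → 1732/743) — stratified by class by default, with an unstratified
mode available.

## The synthetic generator

`generatePeptides()` emulates two-class peptide sets: NACP residues i.i.d.
from a background composition (uniform 1/20 by default, keeping the
generator assumption-light; any composition can be supplied), ACP residues
from the same background exponentially tilted toward K, R, L, A, G, F, W —
the cationic/hydrophobic enrichment typical of real ACPs. A single
`effectSize` knob controls divergence with an exact null at 0. Lengths are
uniform on 10–50. `generateBenchmarkShaped()` reproduces the two study
shapes (138 + 206 and 225 + 2250) for scale rehearsal; its default
`effectSize = 1` is a moderate, imperfectly separable signal chosen once
as a realistic middle ground.

What the generator does *not* emulate: sequence motifs, amphipathic helix
periodicity, secondary structure, and database-specific composition.
Passing the signal-recovery tests therefore shows the pipeline recovers
compositional signal at realistic sizes — not that it reaches any
particular accuracy on curated ACP databases, which differ in motif
structure and curation bias.

## Numerical choices and degenerate inputs

* Encoder rows are exact rational frequencies; normalization is checked to
  1e-12. Length preconditions (`L >= 2` for DPC, `>= 3` for TPC,
  `> lambda` for IPseAAC) fail with the offending record ids.
* `lambda` is validated only against sequence length (`lambda < L`); no
  fixed upper bound is imposed, since any constant cap would exceed the
  shortest admissible peptides.
* The identity threshold discards on *strictly greater* comparison.
* Eigenvalues below numerical zero are clamped by validity checks
  (±1e-9); score covariances are compared at 1e-6.
* All stochastic steps (split, folds, bootstrap, generator) draw from a
  locally seeded RNG that restores the caller's stream.

## Problem sizes in the test-suite and acceptance runs

The shipped checks run the full default pipeline (all four encoders fused,
`lambda = 1`, PCA at 0.95, equal-weight ensemble) on 200 + 200 synthetic
peptides over five seeds for signal recovery (`effectSize = 2`) and five
for the null (`effectSize = 0`); oracle checks use 20 random 50 × 20
matrices for PCA, 400 vote patterns × weight draws, 500 random
label/prediction pairs for metrics, 1000 peptides for normalization, and
200 peptides (30 seeded near-duplicates) for the redundancy filter. These
sizes make every structural claim testable in minutes on one core while
exercising the exact code paths a full-scale run uses.

## Known limitations

* TPC is sparse on short peptides (8000 cells from at most 48 windows), so
  on its own it underperforms, which is why pruned fusion is the default.
* Greedy redundancy reduction is order-dependent by construction
  (longest-first is the standard, deterministic choice).
* The property table is a defensible stand-in, not a recovered original;
  IPseAAC values are therefore comparable *within* this package, across
  property tables only after re-standardization.
* No probability calibration, no ROC/AUC, no class rebalancing — all
  outside the implemented protocol.

## A worked run

```{r example, eval = FALSE}
ps <- generatePeptides(200, 200, effectSize = 2, seed = 11)
pl <- trainPipeline(ps, seed = 11)
pl
round(pipelineMetrics(pl), 3)
ab <- runAblation(ps, seed = 11)
ab[, c("model", "n_features", "accuracy", "mcc")]
```

The vignette leaves these chunks unevaluated so the package builds
quickly; `scripts/acceptance.R` runs the same computations end-to-end and
writes the numbers it measures.
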