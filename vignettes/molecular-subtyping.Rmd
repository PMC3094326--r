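---
title: "Molecular subtyping of breast cancer: models, parameters and validation"
author: "BreastSubtypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular subtyping of breast cancer: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BreastSubtypes)
```

## The problem

Breast cancer is molecularly heterogeneous: tumors with similar clinical
staging can carry very different expression programs and respond very
differently to the same adjuvant chemotherapy. This package implements a
platform-specific workflow that discovers molecular subtypes from bulk
microarray expression, classifies new samples or external datasets by
nearest centroid, derives ER/PR/HER2 receptor status directly from
expression, computes two distant-recurrence risk scores, and supplies the
statistical layer (exact contingency tests, Kaplan-Meier/log-rank
survival comparison, permutation concordance) used to relate subtypes to
clinical outcome. A synthetic cohort generator with known planted truth
makes every stage testable end to end without any external download.

## Preprocessing

`preprocessExpression()` rescales every sample column of a linear-scale
intensity matrix to a common trimmed mean (default 500, the
single-channel array convention; `trimFraction` defaults to 2% per tail)
and applies log2. The output is exactly invariant to per-column positive
rescaling of the input, which is the point of the step: array-to-array
brightness differences are removed before any cross-sample statistics.
`quantileNormalize()` (delegating to `limma::normalizeQuantiles`) then
forces all columns onto the per-rank mean distribution.

One subtlety is deliberate: with tied values, a tie takes the mean of
its rank values. This pooled value is not a member of the reference
multiset, so on tied data the "identical sorted columns" property and
exact idempotence hold only approximately — provably so for any
tie-averaging quantile normalizer. On tie-free (continuous) data both
properties are exact, and the unit tests check them there.

`filterEligible()` encodes the cohort eligibility rule: a sample must
pass all three QC flags (RNA quantity, RNA quality, array quality) and
either have at least three years of follow-up or have died of disease —
short-follow-up deaths are informative and excluded only by mistake.

## Classifier probe selection

Candidate classifier probe-sets are anchored on a configurable list of
*pivotal genes* — genes with established roles in breast cancer biology,
supplied as probe rows of the matrix. A probe is retained when it
correlates with at least one pivotal gene, either linearly
(|Pearson r| ≥ `minAbsLinearR`, default 0.5) or through a degree-2
polynomial fit (R² ≥ `minQuadraticR2`, default 0.5; the quadratic model
nests the linear one), and additionally passes three marginal filters:

* mean log2 intensity ≥ `log2(100)` (reliably measured),
* log2 range ≥ 2 (actually varying),
* Pearson kurtosis m₄/m₂² ≤ 3 (flat or multi-modal density).

Correlation is thresholded on effect size, not p-values: with hundreds
of samples, biologically negligible correlations are formally
significant. The kurtosis cap implements the idea that robust classifier
genes have "more than one peak": a balanced two-point mixture has
kurtosis 1, a uniform density 1.8, a Gaussian 3, spiky unimodal
densities more. The orientation is a cap (keep low kurtosis), and 3 is
the natural reference point. All thresholds sit in
`probeFilterCriteria()` and are configurable; defaults are package
choices, stated here because the selection that matters in practice is
relative (tightening any threshold only removes probes — selection is
monotone, and unit tests assert it).

## Two-step k-means subtyping

`twoStepKmeans()` discovers K subtypes (default 6) in two stages:

1. Euclidean k-means on per-probe z-scores, best of `nRestarts = 100`
   random initializations (lowest within-cluster sum of squares).
2. Per-cluster centroids are computed, every sample is reassigned to the
   centroid with the highest *Spearman* correlation, centroids are
   recomputed, and the loop runs to a fixed point (cap 50 sweeps).

Step 2 is what transfers: rank correlation to a centroid is insensitive
to per-probe location/scale and to monotone distortions between
platforms, which Euclidean distance is not. Clusters emptied during
reassignment are dropped with a warning. The per-probe means and SDs
used for z-scoring are estimated once, at fit time, stored in the
`SubtypeModel`, and re-applied verbatim by `classifyByCentroid()` — new
samples never influence the standardization (no leakage).

Labels I–VI are assigned deterministically: when an ER probe is named,
clusters are ordered by ascending mean ER expression (I = most
ER-negative, matching the convention that subtype I is basal-like and
V–VI are luminal), with cluster size as tie-break; otherwise by
decreasing size. Determinism matters because the adjusted Rand index —
the recovery metric used throughout — is label-permutation invariant,
but humans comparing runs are not.

`classifyByCentroid()` requires at least 50% of the model's classifier
probes to be resolvable in the profile, breaks exact correlation ties
toward the first label (with a warning), and reports the margin between
best and second-best correlation as a confidence measure.
`mapCrossPlatform()` reconstructs the classifier id space from an
external dataset through a probe-to-gene map, averaging multiple
matching rows.

## Marker status from expression

Pooled log2 expression of ER (ESR1), PR (PGR) and HER2 (ERBB2) is
bimodal: an "off" mode and an "expressing" mode. `fitBimodalCutpoint()`
fits a two-component Gaussian mixture (unequal variances) by EM — 20
random restarts, tolerance 1e-8 on the relative log-likelihood change,
cap 2000 iterations, best converged restart kept — and places the
cut-point where the posterior membership probabilities of the two
components are equal (an analytic quadratic root between the means).
The posterior-equality cut was chosen over the density minimum for
stability under weight imbalance; `method = "density-min"` is available
by flag and lands nearby on well-separated mixtures. A fit whose means
are closer than half the pooled SD is flagged *weakly bimodal*. A value
exactly at the cut-point is called negative — the conservative call.
`mclust` provides an independent EM cross-check in the tests; the
package's own EM is the implementation.

## Risk scores

`oncotypeRS()` implements the published 21-gene recurrence-score model
from 16 informative genes on the reference-normalized 0–15 scale: group
scores HER2g = max(8, 0.9·GRB7 + 0.1·HER2), ERg = (0.8·ER + 1.2·PGR +
BCL2 + SCUBE2)/4, PROLIFg = max(6.5, mean of BIRC5, KI67, MYBL2, CCNB1,
AURKA), INVg = mean(CTSL2, MMP11); unscaled = 0.47·HER2g − 0.34·ERg +
1.04·PROLIFg + 0.10·INVg + 0.05·CD68 − 0.08·GSTM1 − 0.07·BAG1; scaled =
clamp(20·(unscaled − 6.7), 0, 100), banded low < 18 ≤ intermediate <
31 ≤ high. How raw log2 expression reaches the 0–15 reference scale is
platform-specific; `scaleToReferenceRange()` provides the documented
default (a single affine map of the cohort's 16-gene submatrix range
onto [0, 15]), and anything else can be supplied upstream.

`mammaprintScore()` is the correlation-with-template score: Pearson
correlation of a tumor profile with a good-prognosis template over the
template genes, high risk if and only if the score is negative (a score
of exactly 0 is low risk). The 70-gene template itself is an input; the
synthetic module supplies one (the mean classifier-probe profile of the
planted low-risk subtypes).

## Exact r×c Fisher test

`fisherExactTest()` computes the exact two-sided test of independence
under the multivariate hypergeometric null with the probability-mass
criterion: the p-value is the total probability of all tables sharing
the observed margins whose probability does not exceed the observed
table's (ties included at a log-space tolerance of 1e-7). This is the
definition that reproduces the published tables of record.

The engine is a network algorithm over the cell-by-cell enumeration
graph. A backward pass computes, for every node (position, remaining row
sums), the minimum, maximum and total (log-sum-exp) completion weight.
The forward pass then prunes entire subtrees: if even the heaviest
completion stays at or below the observed log-probability the subtree's
whole mass is added analytically; if even the lightest exceeds it the
subtree is skipped. Small and moderate tables (including every 2×c
table tried) finish in this exact path.

Tables whose enumeration tree is too large — in practice 4×6 tables with
n in the hundreds, which also overflow `stats::fisher.test`'s FEXACT
workspace — fall back to a binned log-space distribution sweep: the
frontier carries the joint distribution of (remaining row sums,
accumulated log-weight binned at `mergeGrid = 0.02`) in dense per-node
arrays, resolving bins against the backward bounds the moment they
become decidable, so only the ambiguous band around the threshold is
ever stored. The worst-case rounding error is stages × grid/2 in log
space; measured against a table whose exact value is known it is about
1%, and the result agrees with a B = 2×10⁷ Monte-Carlo estimate within
one standard error. A seeded Monte-Carlo mode (`method = "montecarlo"`,
Patefield sampling via `r2dtable`) is available for still larger tables
and is required by the tests to agree with the exact mode within three
Monte-Carlo standard errors. As an internal diagnostic the engine
verifies that the probabilities of all same-margin tables sum to 1
within 1e-9. `fisherExactBruteForce()` is the independent full-
enumeration oracle used to validate the network algorithm on every 2×3
and 3×3 table with total ≤ 12.

## Survival statistics

`kmEstimate()` and `logrankTest()` wrap the survival package's
product-limit estimator and unweighted log-rank test (hypergeometric
variance under ties; chi-square reference with groups − 1 degrees of
freedom), fixing the package conventions: times in years, censored ties
handled after events, zero total events giving p = 1 with a warning
rather than an error. `subtypeConcordance()` tests whether two datasets
share the same per-subtype differential expression pattern: per-gene
subtype means are standardized per gene across subtypes in each dataset,
vectorized and correlated (Pearson); the null distribution comes from
permuting the second dataset's subtype labels B times (default 10000),
with p = (1 + #{r_perm ≥ r_obs})/(B + 1), so the smallest attainable
p-value is 1/(B + 1).

## The synthetic cohort generator

`generateCohort()` draws an expression matrix, clinical table and
planted truth from a `syntheticConfig()` recipe. Defaults describe a
327-sample cohort split 37/34/41/81/41/93 across six subtypes — the
group sizes of the clinical tables the statistics reproduce.

*Expression.* Pivotal genes carry balanced two-level subtype split
patterns (one gene is three-level), at ±2 log2 units (`tauCentroid`)
around baselines in the 8.5–10.5 range with residual SD 0.3. This
shape is a design decision with a reason: the selection filter keeps
low-kurtosis (flat/bimodal) probes, and balanced on/off patterns across
subtype splits — receptor-like biology — are exactly the probes that
pass it, whereas free-form Gaussian subtype patterns are frequently
peaked and would correctly fail. The classifier block consists of
probes anchored on a pivot's split (±jitter, residual SD 0.6), a block
linearly responding to pivotal gene 1 (target |r| = 0.85), and a block
with a symmetric folded (V-shaped) response to the three-level pivotal
gene 2 (target degree-2 R² = 0.8): linear correlation vanishes by
symmetry, the quadratic criterion detects it, and the folded response
stays cleanly bimodal — a literal squared response is slightly
leptokurtic (kurtosis 3.0–3.5) and would trip the kurtosis filter.
700 unstructured noise probes give the false-positive denominator.

*Markers.* ER/PR/HER2 values are drawn from N(7, 0.5²) or N(11, 0.5²)
according to a planted per-sample status, with per-subtype positivity
rates mirroring the clinical tables (subtype I ER-negative through
subtype V uniformly ER+/PR+/HER2−). The implied analytic cut-point
(posterior equality at the realized mixing weights) is stored as truth.
Planted IHC labels flip with probability 0.03 (assay noise) and are
censored to "unknown" with probability 0.05. One consequence is worth
stating: a two-point mixture with weight w has Pearson kurtosis above 3
whenever w(1−w) < 1/6, and PR (≈79% positive) and HER2 (≈23% positive)
sit on that boundary, so "kurtosis < 3" cannot be guaranteed for all
three markers at the study's prevalences; the robust bimodality
criterion is the dip between the modes, which the tests assert for all
three (with the kurtosis bound checked strictly for ER only).

*Survival.* Event times are exponential with subtype-by-regimen hazards
(per year): subtype V has a uniformly low hazard (0.02) insensitive to
chemotherapy; subtype IV responds to CAF (0.04) but poorly to CMF
(0.18); subtype II is uniformly aggressive; untreated hazards are
elevated for the chemo-sensitive subtypes. Censoring is uniform over a
15-year horizon. These values were chosen once so that the planted
contrasts are clinically plausible and detectable at realistic arm
sizes (CAF-vs-CMF log-rank power ≥ 0.8 at 60/arm within subtype IV; no
detectable chemo effect within subtype V), and are not tuned
thereafter.

*Reproducibility.* Structural parameters (split patterns, anchors,
slopes, baselines) are drawn from `cfg$seed` — once per recipe — while
sample-level noise, statuses, covariates and survival come from
`sampleSeed` (defaulting to `cfg$seed`). Two calls with the same config
and different `sampleSeed` therefore yield independent cohorts from the
same planted subtype structure, which is what "classify a fresh cohort
with a fitted model" means.

*What passing tests do and do not show.* The generator emulates the
statistical skeleton the methods assume: well-separated subtype
centroids, pivot-anchored correlation structure, cleanly bimodal
markers, exponential hazards. Real cohorts add batch effects,
probe-level noise that is not Gaussian on the log scale, partially
overlapping subtypes, non-proportional hazards and treatment assignment
confounded with severity. Recovery of planted structure (ARI ≥ 0.9,
cut-points within 0.3 log2 units, ≥ 97% marker call accuracy)
demonstrates correctness of the implementation under its own
assumptions, not clinical performance.

## Numerical choices and degenerate inputs

* Constant probes cannot be z-scored; the subtyping step drops them with
  a warning, and correlation against a constant vector returns `NA`
  (excluded from selection) rather than erroring.
* Exact correlation ties in classification break toward the first label
  in the model's order, with a warning — deterministic and auditable.
* EM restarts that fail to converge are discarded; if none converge the
  fit errors rather than returning a doubtful cut-point. A
  posterior-equality point that falls outside the two means (possible
  under extreme weight imbalance) falls back to the density minimum with
  a warning.
* The Fisher engine refuses tables beyond its state budget with an
  error that names the Monte-Carlo mode, rather than silently
  approximating.
* Problem sizes in the test suite (cohorts of 105–327 samples, ~940
  probes, 2000 null survival simulations, B = 10⁴ permutations, the
  full ≤ 12-total brute-force enumeration) were chosen as the smallest
  that exercise every code path convincingly.

## Known limitations

* K = 6 is a parameter, not a finding of this package; no gap statistic
  or consensus clustering is provided for choosing it.
* The published classifier list (783 probe-sets), pivotal-gene list and
  commercial predictor templates are configuration inputs, not shipped
  data; results on real cohorts depend on supplying them.
* The recurrence-score reference normalization is a linear
  approximation of the assay's reference-gene normalization; scores are
  comparable within a cohort, not across assays.
* Exact Fisher mode on large sparse tables can be expensive (minutes
  for a 4×6 table with n ≈ 330); the binned sweep's ~1% accuracy is
  ample for reported p-values but is not an arbitrary-precision
  computation.
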