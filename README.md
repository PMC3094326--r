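# BreastSubtypes

Microarray-based molecular subtyping of breast cancer, with the
statistics needed to relate subtypes to treatment response.

Breast tumors with identical staging can carry very different expression
programs and respond differently to the same adjuvant chemotherapy.
This package implements a complete, testable subtyping workflow for bulk
log2 expression matrices (probes × samples):

* **Preprocessing** — trimmed-mean scaling to a common target (default
  500), log2 transform, quantile normalization, and cohort eligibility
  filtering (QC flags; ≥ 3 years follow-up unless the patient died of
  disease).
* **Classifier probe selection** — probes linearly (|r| ≥ 0.5) or
  quadratically (degree-2 R² ≥ 0.5) correlated with any of a set of
  *pivotal genes*, then filtered on mean intensity, expression range,
  and Pearson kurtosis m₄/m₂² ≤ 3 (flat/bimodal densities classify
  robustly; spiky unimodal ones do not).
* **Two-step k-means subtyping** — Euclidean k-means on per-probe
  z-scores (best of 100 restarts), then iterated reassignment of every
  sample to the centroid with the highest Spearman correlation; K = 6
  by default, labels I–VI ordered from most ER-negative (basal-like) to
  luminal. Classification of new samples or external platforms goes
  through `classifyByCentroid()` / `mapCrossPlatform()` with the
  fit-time standardization stored in the `SubtypeModel`.
* **Marker status from expression** — a two-component Gaussian mixture
  fitted by EM to the pooled (bimodal) density of ESR1 / PGR / ERBB2;
  the cut-point sits where posterior membership in the two components
  is equal, and values above it are called positive.
* **Recurrence risk scores** — the 21-gene recurrence-score model
  (group scores with floors, RS = clamp(20·(u − 6.7), 0, 100), bands
  low < 18 ≤ intermediate < 31 ≤ high) and the correlation-with-
  good-prognosis-template score (high risk ⇔ score < 0).
* **Statistics** — an exact r×c Fisher (Freeman–Halton) test under the
  probability-mass criterion, implemented as a log-space network
  algorithm with a binned distribution sweep for tables that overflow
  `stats::fisher.test` (a 4×6 table with n = 327 does); Kaplan–Meier
  and log-rank comparisons; permutation-based cross-dataset subtype
  concordance.
* **Synthetic cohorts** — `generateCohort()` plants six expression
  subtypes, pivot-anchored probe blocks, bimodal markers and
  subtype-by-regimen exponential survival with known truth, so the
  whole pipeline is validated end to end without any download.

## Worked example

```r
library(BreastSubtypes)

# a 327-sample cohort with planted truth
cfg <- syntheticConfig(seed = 11)
se  <- generateCohort(cfg)
tr  <- cohortTruth(se)
expr <- as.matrix(SummarizedExperiment::assay(se, 1))

# probe selection anchored on the pivotal genes
probes <- selectClassifierProbes(expr, tr$pivotProbes)
length(probes)
#> [1] 231

# subtype discovery and a fitted centroid model
fit <- twoStepKmeans(expr, k = 6, seed = 42, probes = probes,
                     erProbe = "ESR1")
table(fit$labels)
#>  I  II III  IV   V  VI
#> 37  34  41  81  93  41
mclust::adjustedRandIndex(tr$subtype, fit$labels)
#> [1] 1

# ER status from the bimodal expression density
cp <- fitBimodalCutpoint(expr["ESR1", ], seed = 7, role = "ER")
cp
#> MarkerCutpoint [ER]: cut = 9.066 (log2)
#>   components: N(7.03, 0.50^2) w=0.37 | N(11.06, 0.48^2) w=0.63
calls <- callMarkerStatus(expr["ESR1", ], cp)
mean(calls == tr$markerStatus$ER)
#> [1] 1

# exact Fisher test of marker status against subtype
fisherExactTest(as.matrix(table(calls, fit$labels)))$p.value
#> [1] 6.971111e-51
```

The selected probes are the planted classifier block; the clustering
recovers the planted partition exactly (adjusted Rand index 1, label
names permuting freely); the fitted ER cut-point (9.07) sits at the
planted posterior-equality point between the off (≈7) and expressing
(≈11) modes; and the marker-by-subtype association is overwhelming, as
it is in real cohorts.

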