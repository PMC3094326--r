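test_that("cohort dimensions and determinism follow the recipe", {
  cfg <- smallCohortConfig(seed = 108)
  se <- generateCohort(cfg)
  nProbes <- cfg$nCentroidProbes + cfg$nLinearProbes +
    cfg$nQuadraticProbes + cfg$nPivotalGenes + 3 + 13 + cfg$nNoiseProbes
  expect_identical(dim(se), c(as.integer(nProbes),
                              sum(cfg$nPerSubtype)))
  # same seed twice: identical output
  se2 <- generateCohort(cfg)
  expect_identical(SummarizedExperiment::assay(se, 1),
                   SummarizedExperiment::assay(se2, 1))
  expect_identical(as.data.frame(SummarizedExperiment::colData(se)),
                   as.data.frame(SummarizedExperiment::colData(se2)))
  # different sample seed: same structure/proportions, different noise
  se3 <- generateCohort(cfg, sampleSeed = 999)
  expect_false(identical(SummarizedExperiment::assay(se, 1),
                         SummarizedExperiment::assay(se3, 1)))
  expect_identical(table(cohortTruth(se)$subtype),
                   table(cohortTruth(se3)$subtype))
})

test_that("configuration inconsistencies are rejected", {
  expect_error(syntheticConfig(nPerSubtype = c(10, 10)), "K entries")
  expect_error(syntheticConfig(erPosProb = c(1, 0)), "K entries")
  bad <- smallCohortConfig()
  bad$hazards[2, 2] <- -1
  expect_error(generateCohort(bad), "positive")
})

test_that("marker genes show the planted bimodal pooled density", {
  # full-size cohort: mixing weights are those of the clinical tables
  se <- generateCohort(syntheticConfig(seed = 109))
  expr <- as.matrix(SummarizedExperiment::assay(se, 1))
  for (g in c("ESR1", "PGR", "ERBB2")) {
    v <- expr[g, ]
    # a genuine dip between the modes: density at the midpoint is well
    # below both mode peaks
    d <- stats::density(v)
    dens <- function(x) d$y[which.min(abs(d$x - x))]
    expect_lt(dens(9), 0.6 * max(dens(7), dens(11)))
    # flat/bimodal rather than peaked: kurtosis near or below the
    # two-point bound; only ER's balanced mixture must go clearly below 3
    # (a two-point mixture with weight w has kurtosis > 3 when
    # w(1 - w) < 1/6, which PR's ~79% and HER2's ~23% positivity allow)
    expect_lt(pearsonKurtosis(v), if (g == "ESR1") 3 else 3.6)
  }
})

test_that("survival structure separates treatment-responsive strata", {
  cfg <- smallCohortConfig(seed = 110)
  # subtype V: hazard identical across regimens
  expect_true(all(cfg$hazards["V", ] == cfg$hazards["V", 1]))
  # subtype IV: CAF hazard well below CMF
  expect_lt(cfg$hazards["IV", "CAF"], cfg$hazards["IV", "CMF"])
  set.seed(67)
  a <- drawSurvivalTimes(cfg, "IV", "CAF", 500)
  b <- drawSurvivalTimes(cfg, "IV", "CMF", 500)
  lr <- logrankTest(c(a$time, b$time), c(a$event, b$event),
                    rep(c("CAF", "CMF"), each = 500))
  expect_lt(lr$p.value, 1e-6)
})

test_that("truth report computes recovery metrics and validates inputs", {
  se <- generateCohort(smallCohortConfig(seed = 111))
  tr <- cohortTruth(se)
  # perfect recovery
  rep1 <- truthReport(tr, labels = tr$subtype,
                      cutpoints = tr$cutpoints,
                      markerCalls = tr$markerStatus)
  expect_equal(rep1$ari, 1)
  expect_equal(unname(rep1$cutpointError), rep(0, 3))
  expect_equal(unname(rep1$markerAccuracy), rep(1, 3))
  # random labels have ARI near zero
  set.seed(68)
  rand <- setNames(sample(tr$subtype), names(tr$subtype))
  expect_lt(abs(truthReport(tr, labels = rand)$ari), 0.05)
  # sample mismatch errors
  bad <- tr$subtype[-1]
  expect_error(truthReport(tr, labels = bad), "differ")
})
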