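test_that("linear correlation handles exact and degenerate cases", {
  expect_equal(linearCorrelation(1:3, c(2, 4, 6)), 1)
  expect_equal(linearCorrelation(1:3, c(6, 4, 2)), -1)
  x <- -2:2
  expect_equal(linearCorrelation(x, x^2), 0)
  expect_true(is.na(linearCorrelation(rep(1, 5), 1:5)))
})

test_that("quadratic R2 captures curvature and nests the linear fit", {
  x <- -2:2
  expect_equal(quadraticR2(x, x^2), 1)
  expect_equal(quadraticR2(c(0, 1, 3, 7), 3 * c(0, 1, 3, 7) + 1), 1)
  # independent noise stays near zero under the null
  set.seed(41)
  xs <- rnorm(1000)
  ys <- rnorm(1000)
  expect_lt(quadraticR2(xs, ys), 0.02)
  # degenerate design (two distinct x values)
  expect_true(is.na(quadraticR2(c(1, 1, 2, 2), c(1, 2, 3, 4))))
})

test_that("Pearson kurtosis matches analytic reference values", {
  set.seed(7)
  expect_equal(pearsonKurtosis(rnorm(1e5)), 3, tolerance = 0.1 / 3)
  expect_equal(pearsonKurtosis(runif(1e5)), 1.8, tolerance = 0.05 / 1.8)
  expect_equal(pearsonKurtosis(rep(c(-1, 1), 50)), 1)
  expect_true(is.na(pearsonKurtosis(rep(2, 10))))
  # cross-check against the e1071 moment estimator (excess + 3)
  v <- rnorm(500)
  expect_equal(pearsonKurtosis(v), e1071::kurtosis(v, type = 1) + 3,
               tolerance = 1e-12)
})

test_that("selection recovers planted linear and quadratic blocks exactly", {
  set.seed(13)
  n <- 300
  p1 <- rnorm(n)
  p2 <- rnorm(n)
  r <- 0.9
  lin <- t(sapply(1:50, function(i)
    r * p1 + sqrt(1 - r^2) * rnorm(n)))
  q <- (p2^2 - mean(p2^2)) / sd(p2^2)
  quad <- t(sapply(1:50, function(i)
    sqrt(0.9) * q + sqrt(0.1) * rnorm(n)))
  noise <- matrix(rnorm(900 * n), 900, n)
  m <- rbind(P1 = p1, P2 = p2, lin, quad, noise)
  rownames(m) <- c("P1", "P2", paste0("L", 1:50), paste0("Q", 1:50),
                   paste0("N", 1:900))
  colnames(m) <- paste0("s", 1:n)
  crit <- probeFilterCriteria(0.6, 0.6, -Inf, 0, Inf)
  sel <- selectClassifierProbes(m, c("P1", "P2"), crit)
  expect_setequal(setdiff(sel, c("P1", "P2")),
                  c(paste0("L", 1:50), paste0("Q", 1:50)))

  # with all filters disabled every probe is returned
  all <- selectClassifierProbes(m, c("P1", "P2"),
                                probeFilterCriteria(0, 0, -Inf, 0, Inf))
  expect_setequal(all, rownames(m))

  # monotone: tightening a threshold never adds probes
  tight <- selectClassifierProbes(m, c("P1", "P2"),
                                  probeFilterCriteria(0.8, 0.8, -Inf, 0, Inf))
  expect_true(all(tight %in% sel))

  # permuting samples leaves the selection unchanged
  perm <- sample(n)
  expect_identical(selectClassifierProbes(m[, perm], c("P1", "P2"), crit),
                   sel)
})

test_that("the kurtosis filter keeps bimodal probes and drops heavy tails", {
  set.seed(5)
  n <- 400
  pivot <- rnorm(n)
  bimodal <- 2 * sign(pivot) + rnorm(n, 0, 0.5)      # kurtosis well below 3
  heavy <- pivot * rt(n, df = 3)                     # heavy-tailed
  heavy <- sign(cor(heavy, pivot)) * heavy
  m <- rbind(PIV = pivot, BI = bimodal, HT = heavy)
  colnames(m) <- paste0("s", 1:n)
  expect_lt(pearsonKurtosis(bimodal), 3)
  expect_gt(pearsonKurtosis(heavy), 5)
  crit <- probeFilterCriteria(0.2, 0.2, -Inf, 0, maxKurtosis = 3)
  sel <- selectClassifierProbes(m, "PIV", crit)
  expect_true("BI" %in% sel)
  expect_false("HT" %in% sel)
})

test_that("selection recovers the generator's planted classifier block", {
  cfg <- smallCohortConfig(seed = 101)
  se <- generateCohort(cfg)
  tr <- cohortTruth(se)
  expr <- as.matrix(SummarizedExperiment::assay(se, 1))
  sel <- selectClassifierProbes(expr, tr$pivotProbes)
  sensitivity <- mean(tr$classifierProbes %in% sel)
  noiseProbes <- grep("^NOISE", rownames(expr), value = TRUE)
  fpr <- mean(noiseProbes %in% sel)
  expect_gte(sensitivity, 0.95)
  expect_lte(fpr, 0.01)
})
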