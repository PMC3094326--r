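test_that("exact Fisher p-values match enumeration references", {
  # the observed table is the modal configuration: every table qualifies
  expect_equal(fisherExactTest(rbind(c(14, 11), c(8, 6)))$p.value, 1)
  # diagonal 2x2: p = 2 / choose(10, 5)
  expect_equal(fisherExactTest(rbind(c(5, 0), c(0, 5)))$p.value, 2 / 252,
               tolerance = 1e-10)
  # hand-enumerated hypergeometric sum (adjuvant vs hormonal-therapy table)
  expect_equal(fisherExactTest(rbind(c(3, 25), c(2, 10)))$p.value, 0.6266,
               tolerance = 1e-3)
})

test_that("exact mode agrees with stats::fisher.test on random small tables", {
  set.seed(61)
  for (i in 1:20) {
    nr <- sample(2:3, 1); nc <- sample(2:4, 1)
    tab <- matrix(rpois(nr * nc, 3), nr, nc)
    if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      next
    expect_equal(fisherExactTest(tab)$p.value,
                 stats::fisher.test(tab)$p.value,
                 tolerance = 1e-7, info = paste(tab, collapse = ","))
  }
})

test_that("exact mode equals brute-force enumeration and is permutation invariant", {
  set.seed(62)
  for (i in 1:10) {
    tab <- matrix(rpois(9, 2), 3, 3)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    pNet <- fisherExactTest(tab)$p.value
    pBF <- fisherExactBruteForce(tab)$p
    expect_equal(pNet, pBF, tolerance = 1e-12)
    perm <- tab[sample(3), sample(3)]
    expect_equal(fisherExactTest(perm)$p.value, pNet, tolerance = 1e-12)
  }
})

test_that("the enumeration's same-margin probabilities sum to one", {
  res <- fisherExactTest(rbind(c(9, 11), c(12, 3), c(1, 2), c(0, 1)))
  expect_lt(abs(res$mass.check), 1e-9)
  expect_equal(res$p.value, 0.047, tolerance = 1e-2)
})

test_that("Monte-Carlo mode agrees with exact mode within 3 standard errors", {
  tab <- rbind(c(8, 3, 5), c(2, 9, 4))
  pE <- fisherExactTest(tab)$p.value
  B <- 20000
  pMC <- fisherExactTest(tab, method = "montecarlo", B = B, seed = 9)$p.value
  se <- sqrt(pE * (1 - pE) / B)
  expect_lt(abs(pMC - pE), 3 * se)
})

test_that("count validation rejects malformed tables", {
  expect_error(fisherExactTest(rbind(c(1.5, 2), c(3, 4))), "integers")
  expect_error(fisherExactTest(rbind(c(-1, 2), c(3, 4))), "non-negative")
  expect_error(fisherExactTest(matrix(0, 2, 2)), "positive")
  expect_error(fisherExact2xc(matrix(1, 3, 3)), "2-row")
})

test_that("Kaplan-Meier estimates follow the product-limit formula", {
  # no events: survival stays at 1
  km <- kmEstimate(c(1, 2, 5), c(0, 0, 0))
  expect_equal(km$surv(c(0, 3, 10)), c(1, 1, 1))
  # all events, no censoring: empirical survival function
  km <- kmEstimate(1:3, c(1, 1, 1))
  expect_equal(km$surv(c(1, 2, 3)), c(2 / 3, 1 / 3, 0))
  # single censored observation
  km <- kmEstimate(5, 0)
  expect_equal(km$surv(c(1, 5, 9)), c(1, 1, 1))
  expect_error(kmEstimate(-1, 1), "negative")
  # all-event data equals the empirical survival function (property)
  set.seed(63)
  t <- rexp(40)
  km <- kmEstimate(t, rep(1, 40))
  ts <- sort(t)
  expect_equal(km$surv(ts), 1 - seq_along(ts) / 40)
})

test_that("log-rank test behaves at its boundary cases and under effect", {
  t <- c(1, 2, 3, 4)
  lr <- logrankTest(c(t, t), c(1, 1, 0, 1, 1, 1, 0, 1),
                    rep(c("a", "b"), each = 4))
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p.value, 1)

  expect_warning(lr0 <- logrankTest(c(1, 2), c(0, 0), c("a", "b")),
                 "no events")
  expect_equal(lr0$p.value, 1)

  # hazard ratio 3 at n = 200/arm is detected essentially always
  set.seed(64)
  reject <- replicate(100, {
    ta <- rexp(200, 1); tb <- rexp(200, 3)
    logrankTest(c(ta, tb), rep(1, 400),
                rep(c("a", "b"), each = 200))$p.value < 0.001
  })
  expect_gte(mean(reject), 0.99)

  # two-group statistic equals the squared standardized O-E sum
  set.seed(65)
  tt <- rexp(60); ev <- rbinom(60, 1, 0.8); g <- rep(c("a", "b"), 30)
  sd2 <- survival::survdiff(survival::Surv(tt, ev) ~ g)
  expect_equal(logrankTest(tt, ev, g)$chisq,
               (sd2$obs[1] - sd2$exp[1])^2 / sd2$var[1, 1],
               tolerance = 1e-8)
})

test_that("subtype concordance is exact for self-derived means", {
  cfg <- smallCohortConfig(seed = 106)
  se <- generateCohort(cfg)
  tr <- cohortTruth(se)
  expr <- as.matrix(SummarizedExperiment::assay(se, 1))
  expr <- expr[tr$classifierProbes, ]
  lab <- tr$subtype
  z <- (expr - rowMeans(expr)) / apply(expr, 1, sd)
  meanA <- vapply(levels(lab), function(s)
    rowMeans(z[, lab == s, drop = FALSE]), numeric(nrow(z)))
  res <- subtypeConcordance(meanA, expr, lab, B = 200, seed = 1)
  expect_equal(res$r.obs, 1, tolerance = 1e-10)
  expect_equal(res$p.perm, 1 / 201)

  expect_error(subtypeConcordance(meanA, expr, lab, B = 0), "positive")
  lab2 <- lab; lab2[lab2 == "VI"] <- "V"
  expect_error(subtypeConcordance(meanA, expr, droplevels(lab2), B = 10),
               "absent")
})

test_that("concordance p-values are calibrated under label permutation", {
  cfg <- smallCohortConfig(seed = 107)
  se <- generateCohort(cfg)
  tr <- cohortTruth(se)
  expr <- as.matrix(SummarizedExperiment::assay(se, 1))[tr$classifierProbes, ]
  lab <- tr$subtype
  z <- (expr - rowMeans(expr)) / apply(expr, 1, sd)
  meanA <- vapply(levels(lab), function(s)
    rowMeans(z[, lab == s, drop = FALSE]), numeric(nrow(z)))
  set.seed(66)
  ps <- replicate(25, {
    shuffled <- sample(lab)
    subtypeConcordance(meanA, expr, shuffled, B = 60)$p.perm
  })
  expect_gte(mean(ps > 0.05), 0.8)
})
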