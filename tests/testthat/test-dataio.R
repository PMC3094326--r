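test_that("expression TSV round trip is lossless and order-preserving", {
  m <- tinyExpr(3, 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeExpression(m, path)
  back <- readExpression(path)
  expect_identical(dim(back), c(3L, 2L))
  expect_identical(rownames(back), rownames(m))
  expect_identical(colnames(back), colnames(m))
  expect_equal(back, m)

  m2 <- tinyExpr(20, 5, seed = 9) + pi  # irrational values
  writeExpression(m2, path)
  expect_equal(readExpression(path), m2, tolerance = 1e-12)
})

test_that("malformed expression files are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2", "pA\t1\t2", "pA\t3\t4"), path)
  expect_error(readExpression(path), "pA")
  writeLines(c("probe_id\ts1\ts2", "pA\t1\tx", "pB\t3\t4"), path)
  expect_error(readExpression(path), "non-numeric")
  m <- tinyExpr()
  expect_error(writeExpression(m[0, , drop = FALSE], path), "at least one")
})

test_that("clinical CSV round trip preserves unknown marker levels", {
  cl <- tinyClinical(c("a", "b", "c"))
  cl$er_ihc <- c("pos", "neg", "unknown")
  path <- withr::local_tempfile(fileext = ".csv")
  writeClinical(cl, path)
  back <- readClinical(path)
  expect_equal(back$er_ihc, c("pos", "neg", "unknown"))
  expect_equal(back$followup_years, cl$followup_years)
  expect_identical(back$hormonal_rx, cl$hormonal_rx)
})

test_that("trimmed-mean scaling matches hand arithmetic and is scale invariant", {
  # a column whose trimmed mean is already on target passes through as log2
  x <- c(400, 450, 500, 550, 600)
  m <- cbind(s1 = x)
  rownames(m) <- paste0("p", 1:5)
  out <- preprocessExpression(m, targetTrimmedMean = mean(x),
                              trimFraction = 0)
  expect_equal(out[, 1], log2(x), ignore_attr = TRUE)

  # hand oracle: c(100..500), trim 0: mean 300, factor 500/300
  x <- c(100, 200, 300, 400, 500)
  m <- cbind(s1 = x); rownames(m) <- paste0("p", 1:5)
  out <- preprocessExpression(m, 500, 0)
  expect_equal(out[, 1], log2(x * 500 / 300), ignore_attr = TRUE)

  # per-column positive rescaling of the input leaves the output unchanged
  m <- tinyExpr(30, 4, seed = 2) + 20
  m2 <- sweep(m, 2, c(2, 0.5, 7, 1.3), `*`)
  expect_equal(preprocessExpression(m), preprocessExpression(m2),
               tolerance = 1e-12)

  expect_error(preprocessExpression(m - 100), "strictly positive")
})

test_that("quantile normalization equalizes distributions and is idempotent", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  rownames(m) <- paste0("p", 1:3)
  out <- quantileNormalize(m)
  expect_equal(out[, 1], c(2.5, 3.5, 4.5), ignore_attr = TRUE)
  expect_equal(out[, 2], c(2.5, 3.5, 4.5), ignore_attr = TRUE)

  # identical columns are left unchanged
  m2 <- cbind(s1 = c(5, 1, 9), s2 = c(5, 1, 9))
  rownames(m2) <- paste0("p", 1:3)
  expect_equal(quantileNormalize(m2), m2)

  # ties (tinyExpr rounds to 3 decimals) map to the mean of their rank
  # values: tied inputs share one output
  m3 <- tinyExpr(50, 6, seed = 3)
  q1 <- quantileNormalize(m3)
  for (j in 1:6) {
    dups <- m3[duplicated(m3[, j]), j]
    for (d in dups)
      expect_length(unique(q1[m3[, j] == d, j]), 1)
  }

  # tie-free data: identical sorted columns (the definitional invariant;
  # a tie's pooled value is deliberately outside the reference multiset),
  # exact idempotence, and agreement with limma as oracle
  set.seed(12)
  m4 <- matrix(rnorm(200), 40, 5,
               dimnames = list(paste0("p", 1:40), paste0("s", 1:5)))
  q4 <- quantileNormalize(m4)
  sorted <- apply(q4, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  expect_equal(quantileNormalize(q4), q4, tolerance = 1e-12)
  expect_equal(q4, limma::normalizeQuantiles(m4), ignore_attr = TRUE,
               tolerance = 1e-12)

  expect_warning(one <- quantileNormalize(m3[, 1, drop = FALSE]),
                 ">= 2 samples")
  expect_equal(one, m3[, 1, drop = FALSE])
})

test_that("eligibility combines QC flags with the follow-up exception", {
  ids <- c("s1", "s2", "s3", "s4")
  cl <- tinyClinical(ids)
  cl$followup_years <- c(5, 2, 2, 10)
  cl$dead_of_disease <- c(FALSE, FALSE, TRUE, FALSE)
  qc <- allPassQC(ids)
  # short follow-up excluded unless dead of disease
  expect_identical(filterEligible(cl, qc), c("s1", "s3", "s4"))
  # with no minimum follow-up everything passes QC-clean
  expect_identical(filterEligible(cl, qc, minFollowupYears = 0), ids)
  # QC failure removes a sample regardless of follow-up
  qc$array_ok[4] <- FALSE
  expect_identical(filterEligible(cl, qc), c("s1", "s3"))
  # missing QC record is an error naming the sample
  expect_error(filterEligible(cl, qc[-2, ]), "s2")
})
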