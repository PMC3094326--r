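# planted mixture of K well-separated Gaussian clusters; centerSeed fixes
# the cluster geometry so independent draws share the same structure
makeClusters <- function(k = 6, per = 40, p = 30, sep = 6, sd = 1,
                         seed = 21, centerSeed = 1234) {
  set.seed(centerSeed)
  centers <- matrix(rnorm(p * k, 0, sep * sd / 2), p, k)
  set.seed(seed)
  lab <- rep(seq_len(k), each = per)
  m <- centers[, lab] + matrix(rnorm(p * per * k, 0, sd), p, per * k)
  m <- m + 9  # plausible log2 scale
  dimnames(m) <- list(paste0("g", seq_len(p)),
                      paste0("s", seq_len(per * k)))
  list(m = m, lab = lab)
}

test_that("two-step k-means recovers well-separated planted clusters", {
  fx <- makeClusters()
  fit <- twoStepKmeans(fx$m, k = 6, nRestarts = 25, seed = 4)
  expect_equal(mclust::adjustedRandIndex(fit$labels, fx$lab), 1)
  expect_s4_class(fit$model, "SubtypeModel")
  expect_identical(subtypeLabels(fit$model),
                   c("I", "II", "III", "IV", "V", "VI"))

  # duplicated samples are always co-assigned
  dup <- cbind(fx$m, fx$m)
  colnames(dup) <- paste0("s", seq_len(ncol(dup)))
  fit2 <- twoStepKmeans(dup, k = 6, nRestarts = 10, seed = 4)
  n <- ncol(fx$m)
  expect_identical(as.character(fit2$labels[1:n]),
                   as.character(fit2$labels[n + 1:n]))
})

test_that("two-step k-means validates its inputs", {
  fx <- makeClusters(k = 2, per = 5, p = 4)
  expect_error(twoStepKmeans(fx$m, k = 1, seed = 1), "at least 2")
  expect_error(twoStepKmeans(fx$m, k = 20, seed = 1), "exceeds")
  expect_error(twoStepKmeans(fx$m, k = 2), "seed")
})

test_that("fit is invariant to sample order and per-probe affine rescaling", {
  fx <- makeClusters(per = 20, seed = 8)
  fit <- twoStepKmeans(fx$m, k = 6, nRestarts = 10, seed = 5)
  perm <- sample(ncol(fx$m))
  fitPerm <- twoStepKmeans(fx$m[, perm], k = 6, nRestarts = 10, seed = 5)
  expect_equal(mclust::adjustedRandIndex(fit$labels[perm], fitPerm$labels), 1)

  a <- runif(nrow(fx$m), 0.5, 3)
  b <- rnorm(nrow(fx$m))
  fitAff <- twoStepKmeans(fx$m * a + b, k = 6, nRestarts = 10, seed = 5)
  expect_equal(mclust::adjustedRandIndex(fit$labels, fitAff$labels), 1)
})

test_that("centroids are member means on the standardized scale", {
  m <- tinyExpr(5, 4, seed = 6)
  lab <- c("A", "A", "B", "C")
  model <- computeCentroids(m, lab)
  z <- (m - rowMeans(m)) / apply(m, 1, sd)
  expect_equal(centroids(model)[, "A"], rowMeans(z[, 1:2]),
               ignore_attr = TRUE)
  expect_equal(centroids(model)[, "C"], z[, 4], ignore_attr = TRUE)
  # permuting samples leaves centroids unchanged
  model2 <- computeCentroids(m[, c(3, 1, 4, 2)], lab[c(3, 1, 4, 2)])
  expect_equal(centroids(model2), centroids(model))
  expect_error(computeCentroids(m, c("A", NA, "B", "C")), "label")
})

test_that("centroid classification is exact on the centroids themselves", {
  fx <- makeClusters(per = 15, seed = 10)
  fit <- twoStepKmeans(fx$m, k = 6, nRestarts = 10, seed = 2)
  model <- fit$model
  # back-transform centroids to the raw scale and classify them
  raw <- centroids(model) * model@scale + model@center
  asg <- classifyByCentroid(raw, model, method = "pearson")
  expect_identical(as.character(asg$label), subtypeLabels(model))
  expect_equal(asg$correlation, rep(1, 6), tolerance = 1e-12)

  # held-out half of a fresh draw classifies to the planted structure
  fx2 <- makeClusters(per = 15, seed = 11)
  asg2 <- classifyByCentroid(fx2$m, model)
  expect_gte(mclust::adjustedRandIndex(asg2$label, fx2$lab), 0.98)
})

test_that("classification ties break to the first label with a warning", {
  # identical members for both labels give identical centroids, so every
  # profile is exactly equidistant in correlation: a tie
  set.seed(14)
  base <- matrix(rnorm(20), 5, 4,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  base[, 3:4] <- base[, 1:2]
  model <- computeCentroids(base, c("A", "B", "B", "A"))
  probe <- matrix(rnorm(5), ncol = 1,
                  dimnames = list(paste0("g", 1:5), "q"))
  expect_warning(asg <- classifyByCentroid(probe, model), "tied")
  expect_identical(as.character(asg$label), "A")
  expect_equal(asg$margin, 0)
})

test_that("classification requires half of the classifier probes", {
  fx <- makeClusters(per = 10, p = 20, seed = 12)
  fit <- twoStepKmeans(fx$m, k = 6, nRestarts = 5, seed = 3)
  sub <- fx$m[1:8, , drop = FALSE]   # 40% of probes
  expect_error(classifyByCentroid(sub, fit$model), "40%")
})

test_that("cross-platform mapping averages multi-gene matches", {
  target <- c("t1", "t2", "t3")
  map <- data.frame(probe_id = c("t1", "t2", "t2", "t3"),
                    gene = c("GA", "GB", "GC", "GD"))
  ext <- matrix(1:8, 4, 2,
                dimnames = list(c("GA", "GB", "GC", "GZ"),
                                c("s1", "s2")))
  out <- mapCrossPlatform(target, map, ext)
  expect_equal(out["t1", ], ext["GA", ])
  expect_equal(out["t2", ], (ext["GB", ] + ext["GC", ]) / 2)
  expect_identical(attr(out, "dropped"), "t3")

  # one-to-one mapping is a pure row reordering
  map11 <- data.frame(probe_id = c("t2", "t1"), gene = c("GB", "GA"))
  out11 <- mapCrossPlatform(c("t2", "t1"), map11, ext)
  expect_equal(out11, ext[c("GB", "GA"), ], ignore_attr = TRUE)

  # insufficient coverage is an error
  mapLow <- data.frame(probe_id = "t1", gene = "GA")
  expect_error(mapCrossPlatform(target, mapLow, ext), "50%")
})
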