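## Classifier probe selection: probes correlated (linearly or quadratically)
## with at least one pivotal gene, then filtered on mean intensity, range
## and density kurtosis.  "Low kurtosis" keeps flat / multi-modal probes,
## which discriminate subtypes more robustly than spiky unimodal ones.

#' Pearson correlation with a defined-ness guard
#'
#' Plain product-moment correlation; returns \code{NA} (the "undefined"
#' flag used by probe selection) instead of erroring when either vector is
#' constant.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return correlation in `[-1, 1]`, or \code{NA} if undefined.
#' @export
linearCorrelation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Coefficient of determination of a quadratic fit
#'
#' R-squared of the least-squares degree-2 polynomial regression of `y` on
#' `x`.  Because the quadratic model nests the linear one, a perfectly
#' linear relationship also scores 1.  Degenerate designs (fewer than three
#' distinct `x` values) and constant `y` return \code{NA}.
#'
#' @param x,y numeric vectors of equal length (>= 4).
#' @return R-squared in `[0, 1]`, or \code{NA} if undefined.
#' @export
quadraticR2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (length(unique(x)) < 3 || sd(y) == 0) return(NA_real_)
  X <- cbind(1, x, x * x)
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  max(0, min(1, 1 - rss / tss))
}

#' Pearson (moment) kurtosis
#'
#' The classical population-moment kurtosis m4 / m2^2 (not excess, no
#' small-sample correction): 3 for a normal density, 9/5 for a uniform one,
#' and 1 for a balanced two-point mixture.  Values below 3 indicate flat or
#' multi-modal densities.
#'
#' @param v numeric vector, length >= 4, non-constant.
#' @return kurtosis, or \code{NA} for a constant vector.
#' @export
pearsonKurtosis <- function(v) {
  stopifnot(length(v) >= 4)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((v - m)^4) / m2^2
}

#' Probe filter criteria
#'
#' Bundle of thresholds used by [selectClassifierProbes()].  Correlation
#' with the pivotal genes is judged on effect size rather than p-values
#' (with hundreds of samples, negligible correlations are "significant").
#' Intensity and range act on log2 values; the kurtosis cap keeps flat or
#' bimodal probes.
#'
#' @param minAbsLinearR minimum absolute Pearson correlation, default 0.5.
#' @param minQuadraticR2 minimum quadratic R-squared, default 0.5.
#' @param minMeanIntensity minimum per-probe mean log2 intensity, default
#'   \code{log2(100)}.
#' @param minRange minimum per-probe log2 range (max - min), default 2.
#' @param maxKurtosis maximum Pearson kurtosis, default 3.
#' @return a named list of class \code{ProbeFilterCriteria}.
#' @export
probeFilterCriteria <- function(minAbsLinearR = 0.5,
                                minQuadraticR2 = 0.5,
                                minMeanIntensity = log2(100),
                                minRange = 2,
                                maxKurtosis = 3) {
  crit <- list(minAbsLinearR = minAbsLinearR,
               minQuadraticR2 = minQuadraticR2,
               minMeanIntensity = minMeanIntensity,
               minRange = minRange,
               maxKurtosis = maxKurtosis)
  bad <- names(crit)[!vapply(crit, function(x)
    is.numeric(x) && length(x) == 1 && !is.na(x), logical(1))]
  if (length(bad))
    stop("criteria must be single non-missing numbers: ",
         paste(bad, collapse = ", "))
  stopifnot(minAbsLinearR >= 0, minAbsLinearR <= 1,
            minQuadraticR2 >= 0, minQuadraticR2 <= 1)
  structure(crit, class = "ProbeFilterCriteria")
}

#' Select classifier probe-sets anchored on pivotal genes
#'
#' A probe is selected when (a) it correlates with at least one pivotal
#' gene, either linearly (|r| above threshold) or quadratically (R-squared
#' of the degree-2 fit above threshold), and (b) it passes the mean
#' intensity, expression range, and kurtosis filters.  A pivotal probe is
#' never correlated against itself, but may be selected through another
#' pivot.  The returned order is the matrix row order, so the selection is
#' invariant to sample permutations and deterministic.
#'
#' @param m numeric log2 matrix (probes x samples) or a
#'   \code{SummarizedExperiment} (first assay used).
#' @param pivotProbes character vector of pivotal probe ids, all present in
#'   \code{m}.
#' @param criteria a [probeFilterCriteria()] bundle.
#' @return character vector of selected probe ids (may be empty, with a
#'   warning).
#' @export
setGeneric("selectClassifierProbes",
           function(m, pivotProbes, criteria = probeFilterCriteria())
             standardGeneric("selectClassifierProbes"))

#' @rdname selectClassifierProbes
#' @export
setMethod("selectClassifierProbes", "matrix",
  function(m, pivotProbes, criteria = probeFilterCriteria()) {
    .checkExpressionMatrix(m)
    if (!length(pivotProbes)) stop("pivotProbes must be non-empty")
    missing <- setdiff(pivotProbes, rownames(m))
    if (length(missing))
      stop("pivotal probes absent from matrix: ",
           paste(utils::head(missing, 3), collapse = ", "))
    if (!inherits(criteria, "ProbeFilterCriteria"))
      criteria <- do.call(probeFilterCriteria, as.list(criteria))

    probes <- rownames(m)
    n <- ncol(m)

    # linear correlations, all probes x all pivots in one pass
    tm <- t(m)
    suppressWarnings(rmat <- cor(tm, tm[, pivotProbes, drop = FALSE]))
    rmat[is.na(rmat)] <- 0
    # quadratic R2: one multi-response least-squares fit per pivot
    r2mat <- matrix(0, length(probes), length(pivotProbes),
                    dimnames = list(probes, pivotProbes))
    tss <- colSums(sweep(tm, 2, colMeans(tm))^2)
    for (p in pivotProbes) {
      x <- m[p, ]
      if (length(unique(x)) < 3) next
      X <- cbind(1, x, x * x)
      fit <- lm.fit(X, tm)
      rss <- colSums(fit$residuals^2)
      r2 <- ifelse(tss > 0, 1 - rss / tss, NA_real_)
      r2[is.na(r2)] <- 0
      r2mat[, p] <- pmin(1, pmax(0, r2))
    }
    # a probe is not its own correlation target
    for (p in pivotProbes) {
      rmat[p, p] <- 0
      r2mat[p, p] <- 0
    }

    corrOK <- apply(abs(rmat) >= criteria$minAbsLinearR |
                      r2mat >= criteria$minQuadraticR2, 1, any)

    mu <- rowMeans(m)
    rng <- apply(m, 1, function(v) max(v) - min(v))
    kurt <- apply(m, 1, function(v) {
      k <- pearsonKurtosis(v)
      if (is.na(k)) Inf else k   # constant probes are never "flat"
    })
    keep <- corrOK &
      mu >= criteria$minMeanIntensity &
      rng >= criteria$minRange &
      kurt <= criteria$maxKurtosis
    out <- probes[keep]
    if (!length(out)) warning("no probes passed the selection criteria")
    out
  })

#' @rdname selectClassifierProbes
#' @export
setMethod("selectClassifierProbes", "SummarizedExperiment",
  function(m, pivotProbes, criteria = probeFilterCriteria()) {
    selectClassifierProbes(as.matrix(SummarizedExperiment::assay(m, 1)),
                           pivotProbes, criteria)
  })
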