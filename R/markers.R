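## ER/PR/HER2 positivity from expression: the pooled log2 intensity of each
## marker gene is bimodal (an off mode and an expressing mode); a
## two-component Gaussian mixture is fitted by EM and the cut-point is
## placed where posterior membership in the two components is equal.

.mixLogLik <- function(x, w, mu, sigma) {
  sum(log(w * dnorm(x, mu[1], sigma[1]) +
            (1 - w) * dnorm(x, mu[2], sigma[2])))
}

.emTwoGaussian <- function(x, w, mu, sigma, tol, maxIter) {
  ll <- -Inf
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    d1 <- w * dnorm(x, mu[1], sigma[1])
    d2 <- (1 - w) * dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    if (any(tot == 0) || any(!is.finite(tot))) break
    g <- d1 / tot
    n1 <- sum(g)
    n2 <- length(x) - n1
    if (n1 < 1e-8 || n2 < 1e-8) break
    w <- n1 / length(x)
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    sigma <- sqrt(c(sum(g * (x - mu[1])^2) / n1,
                    sum((1 - g) * (x - mu[2])^2) / n2))
    if (any(sigma < 1e-6)) break
    llNew <- .mixLogLik(x, w, mu, sigma)
    if (is.finite(llNew) && abs(llNew - ll) < tol * (1 + abs(llNew))) {
      ll <- llNew
      converged <- TRUE
      break
    }
    ll <- llNew
  }
  list(w = w, mu = mu, sigma = sigma, logLik = ll, converged = converged)
}

# value(s) where the two components have equal posterior probability:
# w N(x|m1,s1) = (1-w) N(x|m2,s2), a quadratic in x; the root between the
# means is the cut-point.
.posteriorEqualityCut <- function(w, mu, sigma) {
  a <- 1 / (2 * sigma[2]^2) - 1 / (2 * sigma[1]^2)
  b <- mu[1] / sigma[1]^2 - mu[2] / sigma[2]^2
  cc <- mu[2]^2 / (2 * sigma[2]^2) - mu[1]^2 / (2 * sigma[1]^2) +
    log(w / (1 - w)) + log(sigma[2] / sigma[1])
  if (abs(a) < 1e-12) {
    roots <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return(NA_real_)
    roots <- c((-b + sqrt(disc)) / (2 * a), (-b - sqrt(disc)) / (2 * a))
  }
  inside <- roots[roots > mu[1] & roots < mu[2]]
  if (!length(inside)) return(NA_real_)
  inside[1]
}

#' Fit a bimodal cut-point to marker gene expression
#'
#' Fits a two-component univariate Gaussian mixture (unequal variances) by
#' EM, best of \code{nRestarts} random starts, and derives the cut-point.
#' With \code{method = "posterior"} (default) the cut-point is the value
#' between the component means where the posterior membership probabilities
#' are equal; \code{"density-min"} instead uses the minimum of the fitted
#' mixture density between the means.  A fit whose means are closer than
#' half the pooled SD is flagged weakly bimodal.
#'
#' @param values numeric vector of log2 expression, length >= 30.
#' @param nRestarts number of EM restarts, default 20.
#' @param seed integer seed for the random restarts.
#' @param role marker role recorded in the result ("ER", "PR", "HER2", ...).
#' @param method cut-point rule, \code{"posterior"} or \code{"density-min"}.
#' @param tol EM convergence tolerance on the relative log-likelihood
#'   change, default 1e-8.
#' @param maxIter maximum EM iterations per restart, default 2000.
#' @return a [MarkerCutpoint-class].
#' @export
fitBimodalCutpoint <- function(values, nRestarts = 20, seed = NULL,
                               role = "marker",
                               method = c("posterior", "density-min"),
                               tol = 1e-8, maxIter = 2000) {
  method <- match.arg(method)
  x <- as.numeric(values)
  if (length(x) < 30)
    stop("need at least 30 values to fit a bimodal cut-point")
  if (anyNA(x) || any(!is.finite(x))) stop("values must be finite")
  if (!is.null(seed)) set.seed(seed)

  best <- NULL
  qs <- quantile(x, c(0.25, 0.75))
  for (r in seq_len(nRestarts)) {
    mu0 <- sort(c(runif(1, min(x), qs[2]), runif(1, qs[1], max(x))))
    if (diff(mu0) < 1e-3) mu0 <- mu0 + c(-0.1, 0.1)
    s0 <- rep(max(sd(x) / 2, 1e-3), 2)
    fit <- .emTwoGaussian(x, w = 0.5, mu = mu0, sigma = s0,
                          tol = tol, maxIter = maxIter)
    if (fit$converged &&
        (is.null(best) || fit$logLik > best$logLik)) best <- fit
  }
  if (is.null(best))
    stop("EM did not converge in any of the ", nRestarts, " restarts")

  # order components by mean
  ord <- order(best$mu)
  mu <- best$mu[ord]
  sigma <- best$sigma[ord]
  w <- if (ord[1] == 1) best$w else 1 - best$w

  pooled <- sqrt(w * sigma[1]^2 + (1 - w) * sigma[2]^2)
  weak <- (mu[2] - mu[1]) < 0.5 * pooled
  if (weak)
    warning("weakly bimodal: component means closer than 0.5 x pooled SD")

  cut <- if (method == "posterior") {
    .posteriorEqualityCut(w, mu, sigma)
  } else {
    optimize(function(v) w * dnorm(v, mu[1], sigma[1]) +
               (1 - w) * dnorm(v, mu[2], sigma[2]),
             interval = c(mu[1], mu[2]))$minimum
  }
  if (is.na(cut)) {
    warning("posterior-equality point lies outside the modes; ",
            "falling back to the density minimum")
    cut <- optimize(function(v) w * dnorm(v, mu[1], sigma[1]) +
                      (1 - w) * dnorm(v, mu[2], sigma[2]),
                    interval = c(mu[1], mu[2]))$minimum
  }

  new("MarkerCutpoint", role = role, cutpoint = cut, means = mu,
      sds = sigma, weight = w, logLik = best$logLik,
      converged = TRUE, weaklyBimodal = weak)
}

#' Call marker status from expression values
#'
#' A sample is positive when its expression strictly exceeds the cut-point;
#' a value exactly at the cut-point is called negative (the conservative
#' call).
#'
#' @param values numeric vector of log2 expression.
#' @param cut a [MarkerCutpoint-class].
#' @return factor with levels \code{neg}, \code{pos}.
#' @export
callMarkerStatus <- function(values, cut) {
  stopifnot(is(cut, "MarkerCutpoint"))
  factor(ifelse(values > cut@cutpoint, "pos", "neg"),
         levels = c("neg", "pos"))
}
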