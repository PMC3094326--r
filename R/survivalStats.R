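## Survival layer: product-limit estimation, log-rank comparison, and
## permutation-based cross-dataset subtype concordance.  Estimation and
## testing are delegated to the survival package; this layer fixes the
## conventions used throughout (years, censored ties after events,
## chi-square reference for the log-rank statistic).

#' Kaplan-Meier product-limit estimate
#'
#' @param time numeric vector of non-negative follow-up times (years).
#' @param event logical/0-1 vector, TRUE when the endpoint occurred.
#' @return a list with \code{surv} (a right-continuous step function
#'   mapping time to survival probability), and the underlying
#'   \code{survfit} object.
#' @export
kmEstimate <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1)
  if (any(time < 0)) stop("negative survival time")
  event <- as.integer(as.logical(event))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  if (length(fit$time) == 0 || all(fit$n.event == 0)) {
    sf <- function(t) rep(1, length(t))
  } else {
    sf <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  }
  list(surv = sf, fit = fit)
}

#' Log-rank test between survival groups
#'
#' Standard (unweighted) log-rank test over the pooled event times, with
#' the usual hypergeometric variance under ties; the p-value comes from a
#' chi-square reference with (groups - 1) degrees of freedom.  With zero
#' events in total the test is undefined and p = 1 is returned with a
#' warning.
#'
#' @param time,event as in [kmEstimate()].
#' @param group factor/character of group membership (>= 2 non-empty
#'   groups).
#' @return list with \code{chisq}, \code{df}, \code{p.value}.
#' @export
logrankTest <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (any(time < 0)) stop("negative survival time")
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("need at least two non-empty groups")
  event <- as.integer(as.logical(event))
  if (sum(event) == 0) {
    warning("no events in any group; log-rank test undefined, p = 1")
    return(list(chisq = 0, df = nlevels(group) - 1L, p.value = 1))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p.value = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Permutation test of cross-dataset subtype concordance
#'
#' Measures whether two datasets show the same per-subtype differential
#' expression pattern: per-gene subtype means are computed in each dataset
#' and standardized per gene across subtypes, and the observed concordance
#' is the Pearson correlation between the two vectorized (gene x subtype)
#' mean grids over the shared genes.  The null distribution is built by permuting the
#' second dataset's subtype labels across samples \code{B} times;
#' \code{p = (1 + #\{r_perm >= r_obs\}) / (B + 1)}.
#'
#' @param meanA numeric matrix (genes x K) of per-subtype mean expression
#'   in the reference dataset (on any per-gene standardized scale).
#' @param exprB numeric matrix (genes x samples) of the second dataset.
#' @param labelsB subtype labels of the second dataset's samples, using the
#'   same K labels as \code{meanA}'s columns; every subtype must be
#'   present.
#' @param B number of permutations, default 10000.
#' @param seed integer seed.
#' @return list with \code{r.obs}, \code{p.perm}, \code{B}.
#' @export
subtypeConcordance <- function(meanA, exprB, labelsB, B = 10000,
                               seed = NULL) {
  stopifnot(is.matrix(meanA), is.matrix(exprB))
  if (B < 1) stop("B must be a positive permutation count")
  labelsB <- as.factor(labelsB)
  if (length(labelsB) != ncol(exprB))
    stop("labelsB must have one entry per sample of exprB")
  subtypes <- colnames(meanA)
  if (is.null(subtypes)) stop("meanA needs subtype column names")
  absent <- setdiff(subtypes, levels(droplevels(labelsB)))
  if (length(absent))
    stop("subtype absent in dataset B: ", paste(absent, collapse = ", "))
  shared <- intersect(rownames(meanA), rownames(exprB))
  if (!length(shared)) stop("no shared genes between the datasets")

  # both grids are per-gene standardized across subtypes, so the
  # comparison is scale-free in each dataset (per-gene affine differences
  # between platforms cancel)
  zscore <- function(m) {
    mu <- rowMeans(m)
    s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
    s[s == 0] <- 1
    (m - mu) / s
  }
  A <- zscore(meanA[shared, , drop = FALSE])
  Bsub <- exprB[shared, , drop = FALSE]
  groupMeans <- function(lab) {
    zscore(vapply(subtypes, function(s)
      rowMeans(Bsub[, lab == s, drop = FALSE]), numeric(nrow(Bsub))))
  }
  rObs <- cor(as.vector(A), as.vector(groupMeans(labelsB)))

  if (!is.null(seed)) set.seed(seed)
  vA <- as.vector(A)
  rPerm <- vapply(seq_len(B), function(i) {
    cor(vA, as.vector(groupMeans(sample(labelsB))))
  }, numeric(1))
  pPerm <- (1 + sum(rPerm >= rObs)) / (B + 1)
  list(r.obs = rObs, p.perm = pPerm, B = B)
}
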