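## Distant-recurrence risk scores used to contrast molecular subtypes:
## the 21-gene (Oncotype-style) recurrence score computed from 16
## informative genes grouped into HER2, ER, proliferation and invasion
## modules, and a MammaPrint-style correlation score against a
## good-prognosis template profile.

#' Gene symbols of the 16 informative recurrence-score genes
#'
#' Order: HER2 group (GRB7, HER2), ER group (ER, PGR, BCL2, SCUBE2),
#' proliferation group (BIRC5, KI67, MYBL2, CCNB1, AURKA), invasion group
#' (CTSL2, MMP11), and the three singletons CD68, GSTM1, BAG1.
#'
#' @export
oncotypeGenes <- c("GRB7", "HER2", "ER", "PGR", "BCL2", "SCUBE2",
                   "BIRC5", "KI67", "MYBL2", "CCNB1", "AURKA",
                   "CTSL2", "MMP11", "CD68", "GSTM1", "BAG1")

#' Oncotype-style recurrence score
#'
#' Computes the published 21-gene recurrence-score model from
#' reference-normalized expression of the 16 informative genes (0-15
#' scale).  Group scores: \eqn{HER2_g = \max(8, 0.9\,GRB7 + 0.1\,HER2)};
#' \eqn{ER_g = (0.8\,ER + 1.2\,PGR + BCL2 + SCUBE2)/4};
#' \eqn{PROLIF_g = \max(6.5, \mathrm{mean}(BIRC5, KI67, MYBL2, CCNB1,
#' AURKA))}; \eqn{INV_g = \mathrm{mean}(CTSL2, MMP11)}.  The unscaled score
#' is \eqn{0.47\,HER2_g - 0.34\,ER_g + 1.04\,PROLIF_g + 0.10\,INV_g +
#' 0.05\,CD68 - 0.08\,GSTM1 - 0.07\,BAG1}, rescaled to
#' \eqn{RS = \mathrm{clamp}(20 (u - 6.7), 0, 100)} and banded low (< 18),
#' intermediate (18-30.x), high (>= 31).
#'
#' @param x named numeric vector covering [oncotypeGenes], or a numeric
#'   matrix with those gene rownames (one column per sample), on the
#'   reference-normalized 0-15 scale (see [scaleToReferenceRange()]).
#' @return data.frame with columns \code{sample_id}, \code{unscaled},
#'   \code{scaled}, \code{group}.
#' @export
oncotypeRS <- function(x) {
  if (is.numeric(x) && is.null(dim(x)))
    x <- matrix(x, ncol = 1, dimnames = list(names(x), "sample1"))
  stopifnot(is.matrix(x))
  missing <- setdiff(oncotypeGenes, rownames(x))
  if (length(missing))
    stop("missing recurrence-score gene(s): ",
         paste(missing, collapse = ", "))
  if (!all(is.finite(x[oncotypeGenes, ])))
    stop("recurrence-score input must be finite")
  g <- function(gene) x[gene, ]
  her2g <- pmax(8, 0.9 * g("GRB7") + 0.1 * g("HER2"))
  erg <- (0.8 * g("ER") + 1.2 * g("PGR") + g("BCL2") + g("SCUBE2")) / 4
  prolifg <- pmax(6.5, (g("BIRC5") + g("KI67") + g("MYBL2") +
                          g("CCNB1") + g("AURKA")) / 5)
  invg <- (g("CTSL2") + g("MMP11")) / 2
  unscaled <- 0.47 * her2g - 0.34 * erg + 1.04 * prolifg + 0.10 * invg +
    0.05 * g("CD68") - 0.08 * g("GSTM1") - 0.07 * g("BAG1")
  scaled <- pmin(100, pmax(0, 20 * (unscaled - 6.7)))
  group <- cut(scaled, c(-Inf, 18, 31, Inf),
               labels = c("low", "intermediate", "high"), right = FALSE)
  data.frame(sample_id = colnames(x), unscaled = unname(unscaled),
             scaled = unname(scaled), group = unname(group),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Affine rescale of a cohort to the recurrence-score reference range
#'
#' The recurrence-score model expects reference-normalized expression on a
#' 0-15 scale.  This helper maps the observed range of the cohort's
#' informative-gene submatrix linearly onto `[low, high]`.
#'
#' @param m numeric matrix of log2 expression (the 16-gene submatrix).
#' @param low,high target range, default 0 and 15.
#' @return rescaled matrix of the same shape.
#' @export
scaleToReferenceRange <- function(m, low = 0, high = 15) {
  stopifnot(is.numeric(m), all(is.finite(m)), high > low)
  rng <- range(m)
  if (rng[1] == rng[2]) stop("constant matrix cannot be rescaled")
  low + (m - rng[1]) / (rng[2] - rng[1]) * (high - low)
}

#' MammaPrint-style correlation risk score
#'
#' The score of a tumor profile is its Pearson correlation with a
#' good-prognosis template over the template's genes; a score below zero is
#' called high risk, zero or above low risk.  At least half of the template
#' genes must be present in the profile.
#'
#' @param profile named numeric vector, or matrix (genes x samples).
#' @param template named numeric vector, the good-prognosis template.
#' @return data.frame with columns \code{sample_id}, \code{score},
#'   \code{group} (levels \code{low}, \code{high}).
#' @export
mammaprintScore <- function(profile, template) {
  if (is.numeric(profile) && is.null(dim(profile)))
    profile <- matrix(profile, ncol = 1,
                      dimnames = list(names(profile), "sample1"))
  stopifnot(is.matrix(profile), !is.null(names(template)))
  shared <- intersect(names(template), rownames(profile))
  frac <- length(shared) / length(template)
  if (frac < 0.5)
    stop(sprintf("profile covers only %.0f%% of template genes (need >= 50%%)",
                 100 * frac))
  tv <- template[shared]
  if (sd(tv) == 0) stop("template is constant over the shared genes")
  score <- apply(profile[shared, , drop = FALSE], 2, function(v) {
    if (sd(v) == 0) stop("profile is constant over the shared genes")
    cor(v, tv)
  })
  data.frame(sample_id = colnames(profile), score = unname(score),
             group = factor(ifelse(score < 0, "high", "low"),
                            levels = c("low", "high")),
             stringsAsFactors = FALSE, row.names = NULL)
}
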