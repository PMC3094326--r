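## Two-step k-means subtype discovery and nearest-centroid classification.
## Step 1 is ordinary Euclidean k-means on per-probe z-scores (best of many
## random restarts); step 2 replaces the Euclidean assignment with rank
## (Spearman) correlation to the cluster centroids, iterated to a fixed
## point -- correlation-based assignment is what transfers across platforms.

.rowSds <- function(m) {
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
}

.standardize <- function(m, center, scale) (m - center) / scale

#' Discover molecular subtypes by two-step k-means
#'
#' Step 1 runs k-means (Euclidean distance, per-probe z-scored data) over
#' \code{nRestarts} random initializations and keeps the solution with the
#' lowest within-cluster sum of squares.  Step 2 computes per-cluster
#' centroids, reassigns every sample to the centroid with the highest
#' Spearman correlation, recomputes centroids, and iterates to a fixed
#' point (at most \code{maxIter} sweeps).  Clusters emptied by reassignment
#' are dropped with a warning.  The run is deterministic given \code{seed}.
#'
#' Labels are Roman numerals assigned by a deterministic rule: when
#' \code{erProbe} is given, clusters are ordered by ascending mean ER
#' expression (subtype I = most ER-negative, matching the convention that
#' subtype I is basal-like and subtypes V-VI are luminal); otherwise by
#' decreasing cluster size.
#'
#' @param m log2 expression matrix (probes x samples), already restricted
#'   to classifier probes (or use \code{probes} to subset), or a
#'   \code{SummarizedExperiment}.
#' @param k number of subtypes, default 6.
#' @param nRestarts k-means random restarts, default 100.
#' @param seed integer seed (mandatory; all stochastic steps depend on it).
#' @param probes optional character vector restricting rows of \code{m}.
#' @param erProbe optional id of an estrogen-receptor probe used to order
#'   the subtype labels.
#' @param maxIter maximum step-2 reassignment sweeps, default 50.
#' @return a list with \code{labels} (factor of subtype labels, named by
#'   sample) and \code{model} (a [SubtypeModel-class]).
#' @export
setGeneric("twoStepKmeans",
           function(m, k = 6, nRestarts = 100, seed, probes = NULL,
                    erProbe = NULL, maxIter = 50)
             standardGeneric("twoStepKmeans"))

#' @rdname twoStepKmeans
#' @export
setMethod("twoStepKmeans", "matrix",
  function(m, k = 6, nRestarts = 100, seed, probes = NULL, erProbe = NULL,
           maxIter = 50) {
    .checkExpressionMatrix(m)
    if (missing(seed) || is.null(seed)) stop("seed is mandatory")
    if (k < 2) stop("k must be at least 2")
    full <- m
    if (!is.null(probes)) {
      missing <- setdiff(probes, rownames(m))
      if (length(missing))
        stop("probes absent from matrix: ",
             paste(utils::head(missing, 3), collapse = ", "))
      m <- m[probes, , drop = FALSE]
    }
    if (ncol(m) < k) stop("k exceeds the number of samples")

    center <- rowMeans(m)
    scale <- .rowSds(m)
    if (any(scale == 0)) {
      warning("dropping ", sum(scale == 0), " constant probe(s)")
      keep <- scale > 0
      m <- m[keep, , drop = FALSE]
      center <- center[keep]
      scale <- scale[keep]
    }
    z <- .standardize(m, center, scale)

    set.seed(seed)
    km <- kmeans(t(z), centers = k, nstart = nRestarts, iter.max = 100)
    assign <- km$cluster

    # step 2: Spearman-correlation reassignment to centroids, to fixed point
    for (it in seq_len(maxIter)) {
      cents <- vapply(sort(unique(assign)), function(cl)
        rowMeans(z[, assign == cl, drop = FALSE]), numeric(nrow(z)))
      colnames(cents) <- sort(unique(assign))
      cors <- cor(z, cents, method = "spearman")
      best <- max.col(cors, ties.method = "first")
      ties <- rowSums(cors == cors[cbind(seq_len(nrow(cors)), best)]) > 1
      if (any(ties))
        warning(sum(ties), " sample(s) tied between centroids; ",
                "assigned to the first label in order")
      newAssign <- as.integer(colnames(cents))[best]
      kept <- sort(unique(newAssign))
      if (length(kept) < length(unique(assign)))
        warning("cluster(s) emptied during reassignment; k reduced to ",
                length(kept))
      done <- identical(newAssign, assign)
      assign <- newAssign
      if (done) break
    }

    clusters <- sort(unique(assign))
    sizes <- vapply(clusters, function(cl) sum(assign == cl), integer(1))
    if (!is.null(erProbe)) {
      if (!erProbe %in% rownames(full))
        stop("erProbe not found in matrix: ", erProbe)
      erMean <- vapply(clusters, function(cl)
        mean(full[erProbe, assign == cl]), numeric(1))
      ord <- order(erMean, -sizes)
    } else {
      ord <- order(-sizes, clusters)
    }
    labels <- as.character(utils::as.roman(seq_along(clusters)))
    labMap <- setNames(labels, clusters[ord])
    lab <- factor(labMap[as.character(assign)], levels = labels)
    names(lab) <- colnames(m)

    model <- computeCentroids(m, lab, center = center, scale = scale)
    list(labels = lab, model = model)
  })

#' @rdname twoStepKmeans
#' @export
setMethod("twoStepKmeans", "SummarizedExperiment",
  function(m, k = 6, nRestarts = 100, seed, probes = NULL, erProbe = NULL,
           maxIter = 50) {
    twoStepKmeans(as.matrix(SummarizedExperiment::assay(m, 1)), k = k,
                  nRestarts = nRestarts, seed = seed, probes = probes,
                  erProbe = erProbe, maxIter = maxIter)
  })

#' Compute subtype centroids from a labeled expression matrix
#'
#' The centroid of a subtype is the per-probe arithmetic mean of its member
#' columns on the standardized (z-score) scale.  When \code{center} and
#' \code{scale} are not supplied they are estimated from \code{m}; they are
#' stored in the model and re-applied verbatim at classification time.
#'
#' @param m log2 expression matrix (probes x samples).
#' @param labels factor/character of subtype labels, one per sample; every
#'   level must have at least one member and no label may be missing.
#' @param center,scale optional per-probe standardization constants.
#' @return a [SubtypeModel-class].
#' @export
computeCentroids <- function(m, labels, center = NULL, scale = NULL) {
  .checkExpressionMatrix(m)
  if (length(labels) != ncol(m))
    stop("labels must have one entry per sample")
  if (anyNA(labels)) stop("unknown (missing) label in input")
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (is.null(center)) center <- rowMeans(m)
  if (is.null(scale)) scale <- .rowSds(m)
  if (any(scale <= 0)) stop("constant probes cannot be standardized")
  z <- .standardize(m, center, scale)
  cents <- vapply(levels(labels), function(l)
    rowMeans(z[, labels == l, drop = FALSE]), numeric(nrow(z)))
  new("SubtypeModel",
      classifierProbes = rownames(m),
      centroids = unname(cents),
      labels = levels(labels),
      center = unname(center),
      scale = unname(scale))
}

#' Classify samples by nearest subtype centroid
#'
#' Profiles are standardized with the model's fit-time per-probe constants
#' and assigned to the subtype whose centroid they correlate with best
#' (Spearman by default; Pearson by flag).  At least half of the model's
#' classifier probes must be resolvable in the profiles.  Ties are broken
#' by label order with a warning.  The margin (best minus second-best
#' correlation) is reported as an assignment-confidence measure.
#'
#' @param profiles log2 expression matrix (probes x samples), a single
#'   named numeric vector, or a \code{SummarizedExperiment}.
#' @param model a [SubtypeModel-class].
#' @param method correlation type, \code{"spearman"} (default) or
#'   \code{"pearson"}.
#' @return data.frame with columns \code{sample_id}, \code{label},
#'   \code{correlation}, \code{margin}.
#' @export
setGeneric("classifyByCentroid",
           function(profiles, model, method = c("spearman", "pearson"))
             standardGeneric("classifyByCentroid"))

#' @rdname classifyByCentroid
#' @export
setMethod("classifyByCentroid", "matrix",
  function(profiles, model, method = c("spearman", "pearson")) {
    method <- match.arg(method)
    stopifnot(is(model, "SubtypeModel"))
    probes <- model@classifierProbes
    ov <- intersect(probes, rownames(profiles))
    frac <- length(ov) / length(probes)
    if (frac < 0.5)
      stop(sprintf("only %.0f%% of classifier probes resolvable (need >= 50%%)",
                   100 * frac))
    idx <- match(ov, probes)
    z <- .standardize(profiles[ov, , drop = FALSE],
                      model@center[idx], model@scale[idx])
    cents <- model@centroids[idx, , drop = FALSE]
    cors <- cor(z, cents, method = method)
    best <- max.col(cors, ties.method = "first")
    ties <- rowSums(abs(cors - cors[cbind(seq_len(nrow(cors)), best)]) <
                      1e-12) > 1
    if (any(ties))
      warning(sum(ties), " sample(s) tied between centroids; ",
              "assigned to the first label in order")
    sorted <- t(apply(cors, 1, sort, decreasing = TRUE))
    data.frame(
      sample_id = colnames(profiles),
      label = factor(model@labels[best], levels = model@labels),
      correlation = cors[cbind(seq_len(nrow(cors)), best)],
      margin = sorted[, 1] - sorted[, 2],
      stringsAsFactors = FALSE, row.names = NULL)
  })

#' @rdname classifyByCentroid
#' @export
setMethod("classifyByCentroid", "numeric",
  function(profiles, model, method = c("spearman", "pearson")) {
    classifyByCentroid(matrix(profiles, ncol = 1,
                              dimnames = list(names(profiles), "sample1")),
                       model, method)
  })

#' @rdname classifyByCentroid
#' @export
setMethod("classifyByCentroid", "SummarizedExperiment",
  function(profiles, model, method = c("spearman", "pearson")) {
    classifyByCentroid(as.matrix(SummarizedExperiment::assay(profiles, 1)),
                       model, method)
  })

#' Map an external expression dataset onto a target probe id space
#'
#' Cross-platform validation requires expressing an external dataset on the
#' classifier's probe ids.  Each target probe is mapped through a
#' probe-to-gene relation; when several external rows match one target
#' probe their average intensity is used.  Target probes with no match are
#' dropped and reported; mapping fewer than half of the targets is an
#' error.
#'
#' @param targetProbeIds character vector of probe ids to reconstruct.
#' @param geneMap data.frame with columns \code{probe_id}, \code{gene}.
#' @param external numeric matrix whose rownames are gene (or other) ids
#'   referenced by \code{geneMap$gene}.
#' @return numeric matrix on the target probe id space (dropped ids are in
#'   attribute \code{"dropped"}).
#' @export
mapCrossPlatform <- function(targetProbeIds, geneMap, external) {
  stopifnot(is.data.frame(geneMap),
            all(c("probe_id", "gene") %in% colnames(geneMap)))
  .checkExpressionMatrix(external, "external matrix")
  covered <- intersect(targetProbeIds, geneMap$probe_id)
  if (length(covered) / length(targetProbeIds) < 0.5)
    stop(sprintf("gene map covers only %.0f%% of target ids (need >= 50%%)",
                 100 * length(covered) / length(targetProbeIds)))
  rows <- lapply(targetProbeIds, function(p) {
    genes <- geneMap$gene[geneMap$probe_id == p]
    hits <- intersect(genes, rownames(external))
    if (!length(hits)) return(NULL)
    colMeans(external[hits, , drop = FALSE])
  })
  matched <- !vapply(rows, is.null, logical(1))
  if (!any(matched)) stop("no target id matches any external row")
  dropped <- targetProbeIds[!matched]
  if (length(dropped))
    message(length(dropped), " target id(s) had no external match and were dropped")
  out <- do.call(rbind, rows[matched])
  rownames(out) <- targetProbeIds[matched]
  attr(out, "dropped") <- dropped
  out
}
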