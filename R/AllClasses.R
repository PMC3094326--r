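#' SubtypeModel: centroids of molecular subtypes over a classifier probe set
#'
#' Holds everything needed to assign new samples to molecular subtypes by
#' nearest-centroid correlation: the classifier probe identifiers, one
#' centroid column per subtype on the standardized (per-probe z-score) scale,
#' the ordered subtype label vocabulary, and the per-probe center/scale
#' constants estimated at fit time.  Storing the fit-time standardization in
#' the model and re-applying it at classification time prevents information
#' leaking from the samples being classified.
#'
#' @slot classifierProbes character vector of probe identifiers (rows of
#'   \code{centroids}).
#' @slot centroids numeric matrix (probes x K) of subtype centroids on the
#'   standardized scale.
#' @slot labels character vector of K distinct subtype labels ("I".."VI" for
#'   K = 6), in a deterministic order.
#' @slot center,scale numeric vectors of per-probe standardization constants
#'   (raw value is transformed as \code{(x - center) / scale}).
#'
#' @seealso [twoStepKmeans()], [computeCentroids()], [classifyByCentroid()]
#' @export
setClass("SubtypeModel",
  representation(
    classifierProbes = "character",
    centroids = "matrix",
    labels = "character",
    center = "numeric",
    scale = "numeric"
  )
)

setValidity("SubtypeModel", function(object) {
  msg <- character()
  K <- ncol(object@centroids)
  if (K < 2) msg <- c(msg, "a SubtypeModel needs at least 2 centroids")
  if (nrow(object@centroids) != length(object@classifierProbes))
    msg <- c(msg, "centroid rows must match classifierProbes")
  if (anyDuplicated(object@classifierProbes))
    msg <- c(msg, "classifierProbes must be unique")
  if (!all(is.finite(object@centroids)))
    msg <- c(msg, "centroids must be finite")
  if (length(object@labels) != K || anyDuplicated(object@labels))
    msg <- c(msg, "labels must be distinct, one per centroid")
  if (length(object@center) != length(object@classifierProbes) ||
      length(object@scale) != length(object@classifierProbes))
    msg <- c(msg, "center/scale must have one entry per probe")
  if (any(!is.finite(object@scale)) || any(object@scale <= 0))
    msg <- c(msg, "scale entries must be positive and finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn SubtypeModel number of subtypes
#' @param x a \code{SubtypeModel}
#' @export
setMethod("length", "SubtypeModel", function(x) ncol(x@centroids))

setMethod("show", "SubtypeModel", function(object) {
  cat("SubtypeModel with", ncol(object@centroids), "subtypes (",
      paste(object@labels, collapse = ", "), ")\n")
  cat("  classifier probes:", length(object@classifierProbes), "\n")
})

#' Accessors for SubtypeModel
#'
#' \code{classifierProbes} returns the probe identifiers, \code{centroids}
#' the standardized centroid matrix with labels as column names, and
#' \code{subtypeLabels} the ordered label vocabulary.
#'
#' @param object a \code{SubtypeModel}
#' @return character vector, matrix, or character vector respectively.
#' @export
classifierProbes <- function(object) {
  stopifnot(is(object, "SubtypeModel"))
  object@classifierProbes
}

#' @rdname classifierProbes
#' @export
centroids <- function(object) {
  stopifnot(is(object, "SubtypeModel"))
  m <- object@centroids
  dimnames(m) <- list(object@classifierProbes, object@labels)
  m
}

#' @rdname classifierProbes
#' @export
subtypeLabels <- function(object) {
  stopifnot(is(object, "SubtypeModel"))
  object@labels
}

#' MarkerCutpoint: bimodal expression cut-point for a clinical marker gene
#'
#' The result of fitting a two-component Gaussian mixture to the pooled
#' expression of a marker gene (ER/PR/HER2) and locating the value between
#' the component means where the posterior membership probabilities are
#' equal.  Samples above the cut-point are called positive.
#'
#' @slot role marker role, one of "ER", "PR", "HER2" (free text allowed).
#' @slot cutpoint the log2 expression threshold, strictly between the means.
#' @slot means,sds numeric length-2: component means (ascending) and SDs.
#' @slot weight mixing weight of the lower component, in (0, 1).
#' @slot logLik log-likelihood of the best converged EM fit.
#' @slot converged logical, TRUE when EM met its tolerance.
#' @slot weaklyBimodal logical, TRUE when the means are closer than half the
#'   pooled SD (the cut-point is then unstable).
#'
#' @seealso [fitBimodalCutpoint()], [callMarkerStatus()]
#' @export
setClass("MarkerCutpoint",
  representation(
    role = "character",
    cutpoint = "numeric",
    means = "numeric",
    sds = "numeric",
    weight = "numeric",
    logLik = "numeric",
    converged = "logical",
    weaklyBimodal = "logical"
  )
)

setValidity("MarkerCutpoint", function(object) {
  msg <- character()
  if (length(object@means) != 2 || length(object@sds) != 2)
    msg <- c(msg, "means and sds must have length 2")
  if (length(object@cutpoint) != 1 || !is.finite(object@cutpoint))
    msg <- c(msg, "cutpoint must be a single finite number")
  else if (object@cutpoint <= min(object@means) ||
           object@cutpoint >= max(object@means))
    msg <- c(msg, "cutpoint must lie strictly between the component means")
  if (object@weight <= 0 || object@weight >= 1)
    msg <- c(msg, "weight must be in (0, 1)")
  if (any(object@sds <= 0)) msg <- c(msg, "component SDs must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MarkerCutpoint", function(object) {
  cat(sprintf("MarkerCutpoint [%s]: cut = %.3f (log2)\n",
              object@role, object@cutpoint))
  cat(sprintf("  components: N(%.2f, %.2f^2) w=%.2f | N(%.2f, %.2f^2) w=%.2f\n",
              object@means[1], object@sds[1], object@weight,
              object@means[2], object@sds[2], 1 - object@weight))
  if (object@weaklyBimodal) cat("  warning: weakly bimodal fit\n")
})

#' @describeIn MarkerCutpoint extract the cut-point value
#' @param object a \code{MarkerCutpoint}
#' @export
cutpoint <- function(object) {
  stopifnot(is(object, "MarkerCutpoint"))
  object@cutpoint
}
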