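## Reading, writing, preprocessing and cohort eligibility filtering.
## Expression matrices are numeric probes x samples grids with unique row
## (probe) and column (sample) identifiers; values are log2 intensities
## after preprocessing.

.checkExpressionMatrix <- function(m, what = "expression matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stop(what, " must be a numeric matrix")
  if (nrow(m) == 0L || ncol(m) == 0L)
    stop(what, " must have at least one probe and one sample")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " must have probe rownames and sample colnames")
  dup <- rownames(m)[duplicated(rownames(m))]
  if (length(dup))
    stop("duplicated probe id: ", dup[1])
  dup <- colnames(m)[duplicated(colnames(m))]
  if (length(dup))
    stop("duplicated sample id: ", dup[1])
  if (!all(is.finite(m)))
    stop(what, " contains missing or non-finite values")
  invisible(m)
}

#' Read an expression matrix from a tab-separated file
#'
#' The expected layout is a header row of sample identifiers, a first column
#' of probe identifiers, and tab-separated numeric intensities; row and
#' column order are preserved.  Duplicated identifiers and non-numeric cells
#' are hard errors naming the offender.
#'
#' @param path path to a TSV file.
#' @return numeric matrix (probes x samples) with probe rownames and sample
#'   colnames.
#' @seealso [writeExpression()]
#' @export
readExpression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) stop("expression file needs a probe column and >= 1 sample")
  probes <- df[[1]]
  vals <- df[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(probes, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    x <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(x) & !is.na(vals[[j]]))
    if (length(bad))
      stop("non-numeric value at row ", bad[1], " (probe ", probes[bad[1]],
           "), column ", colnames(vals)[j])
    m[, j] <- x
  }
  .checkExpressionMatrix(m)
}

#' Write an expression matrix to a tab-separated file
#'
#' Values are written with full double precision (15 significant digits) so
#' that a write/read round trip is lossless for practical purposes.
#'
#' @param m numeric matrix (probes x samples) with dimnames.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeExpression <- function(m, path) {
  .checkExpressionMatrix(m)
  df <- data.frame(probe_id = rownames(m),
                   format(m, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("probe_id", colnames(m))
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

.clinicalColumns <- c(
  "sample_id", "age_years", "t_stage", "n_stage", "m_stage", "tnm_stage",
  "nuclear_grade", "er_ihc", "pr_ihc", "her2_ihc", "chemo_regimen",
  "hormonal_rx", "radiation_rx", "followup_years", "dead_of_disease",
  "mfs_time_years", "mfs_event", "os_time_years", "os_event")

#' Read or write a clinical annotation table
#'
#' Clinical tables are CSV files with one row per sample and the exact
#' column set used throughout the package: identifiers, age, TNM staging,
#' nuclear grade, ER/PR/HER2 immunohistochemistry calls
#' (\code{pos}/\code{neg}/\code{unknown}), treatment flags, follow-up and
#' the metastasis-free / overall survival times (years) and event flags.
#'
#' @param path CSV path.
#' @return \code{readClinical}: a data.frame with the canonical columns.
#' @export
readClinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.clinicalColumns, colnames(df))
  if (length(missing))
    stop("clinical table lacks columns: ", paste(missing, collapse = ", "))
  df <- df[, .clinicalColumns]
  for (col in c("hormonal_rx", "radiation_rx", "dead_of_disease",
                "mfs_event", "os_event"))
    df[[col]] <- as.logical(df[[col]])
  for (col in c("followup_years", "mfs_time_years", "os_time_years")) {
    if (any(df[[col]] < 0, na.rm = TRUE))
      stop("negative time in column ", col)
  }
  df
}

#' @rdname readClinical
#' @param clinical data.frame as returned by [readClinical()] or
#'   [generateCohort()].
#' @return \code{writeClinical}: the path, invisibly.
#' @export
writeClinical <- function(clinical, path) {
  missing <- setdiff(.clinicalColumns, colnames(clinical))
  if (length(missing))
    stop("clinical table lacks columns: ", paste(missing, collapse = ", "))
  write.csv(clinical[, .clinicalColumns], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Scale to a trimmed mean and log2-transform
#'
#' Standard single-channel array preprocessing: every sample column of the
#' linear-scale intensity matrix is rescaled so that its trimmed mean equals
#' \code{targetTrimmedMean} (500 by default, the MAS5 convention), then the
#' whole matrix is transformed to log2.  The output is invariant to
#' per-column positive rescaling of the input up to an additive constant of
#' zero, i.e. exactly invariant.
#'
#' @param raw numeric matrix of strictly positive linear-scale intensities.
#' @param targetTrimmedMean positive scalar, the post-scaling trimmed mean.
#' @param trimFraction fraction trimmed from each tail in `[0, 0.25)`;
#'   default 0.02.
#' @return log2-scale matrix of the same shape.
#' @export
setGeneric("preprocessExpression",
           function(raw, targetTrimmedMean = 500, trimFraction = 0.02)
             standardGeneric("preprocessExpression"))

#' @rdname preprocessExpression
#' @export
setMethod("preprocessExpression", "matrix",
  function(raw, targetTrimmedMean = 500, trimFraction = 0.02) {
    .checkExpressionMatrix(raw, "raw intensity matrix")
    if (any(raw <= 0)) stop("raw intensities must be strictly positive")
    stopifnot(targetTrimmedMean > 0,
              trimFraction >= 0, trimFraction < 0.25)
    tm <- apply(raw, 2, mean, trim = trimFraction)
    scaled <- sweep(raw, 2, targetTrimmedMean / tm, `*`)
    log2(scaled)
  })

#' Quantile-normalize an expression matrix
#'
#' Forces every sample column to share the same distribution: the per-rank
#' mean across columns.  Ties within a column receive the mean of their rank
#' values.  A single-sample matrix is returned unchanged with a warning.
#' The operation is idempotent.
#'
#' @param m numeric matrix (probes x samples).
#' @return matrix of the same shape with identical per-column sorted values.
#' @export
setGeneric("quantileNormalize",
           function(m) standardGeneric("quantileNormalize"))

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "matrix", function(m) {
  .checkExpressionMatrix(m)
  if (ncol(m) < 2) {
    warning("quantile normalization needs >= 2 samples; returning input")
    return(m)
  }
  # per-rank mean of the sorted columns; a tie takes the mean of its rank
  # values (limma's ties=TRUE behaviour).  On tie-free data the transform
  # is exactly idempotent; a tie's pooled value necessarily perturbs the
  # reference distribution, so idempotence is only approximate under ties.
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
})

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "SummarizedExperiment", function(m) {
  se <- m
  SummarizedExperiment::assay(se, 1) <-
    quantileNormalize(as.matrix(SummarizedExperiment::assay(se, 1)))
  se
})

#' Apply quality-control and follow-up eligibility rules to a cohort
#'
#' A sample is eligible when it passes every QC flag (RNA quantity, RNA
#' quality, array quality) and either has at least \code{minFollowupYears}
#' of follow-up or died of the disease (short-follow-up deaths are
#' informative and therefore retained).
#'
#' @param clinical clinical data.frame (needs \code{sample_id},
#'   \code{followup_years}, \code{dead_of_disease}).
#' @param qc data.frame with columns \code{sample_id}, \code{rna_ok},
#'   \code{rna_sufficient}, \code{array_ok}; every clinical sample must have
#'   a record.
#' @param minFollowupYears minimum follow-up, default 3 years.
#' @return character vector of eligible sample ids, in input order.
#' @export
filterEligible <- function(clinical, qc, minFollowupYears = 3) {
  stopifnot(is.data.frame(clinical), is.data.frame(qc))
  need <- c("sample_id", "rna_ok", "rna_sufficient", "array_ok")
  missing <- setdiff(need, colnames(qc))
  if (length(missing))
    stop("QC table lacks columns: ", paste(missing, collapse = ", "))
  idx <- match(clinical$sample_id, qc$sample_id)
  if (anyNA(idx))
    stop("missing QC record for sample ",
         clinical$sample_id[which(is.na(idx))[1]])
  qc <- qc[idx, ]
  passQC <- qc$rna_ok & qc$rna_sufficient & qc$array_ok
  keep <- passQC &
    (clinical$followup_years >= minFollowupYears |
       isTRUE_vec(clinical$dead_of_disease))
  clinical$sample_id[keep]
}

# vectorised isTRUE: NA treated as FALSE
isTRUE_vec <- function(x) !is.na(x) & x
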