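## Synthetic breast-cancer cohort generator.  Plants the statistical
## structure the analysis pipeline assumes -- six expression subtypes,
## pivot-anchored classifier probe blocks (linear and quadratic), bimodal
## ER/PR/HER2 marker genes, a recurrence-score gene panel, and
## subtype-by-regimen exponential survival -- so that every stage of the
## pipeline can be validated against known truth without any download.

#' Synthetic cohort configuration
#'
#' Returns the full generative recipe for [generateCohort()].  The defaults
#' describe a cohort of 327 samples split over six subtypes (37, 34, 41,
#' 81, 41, 93), mirroring a realistic single-institution case series, with:
#' 23 pivotal genes carrying subtype-specific mean shifts (SD
#' \code{tauCentroid} log2 units across subtypes); a classifier block of
#' probes that are either noisy linear transforms of pivotal gene 1,
#' noisy quadratic transforms of pivotal gene 2, or subtype centroids plus
#' noise; unstructured noise probes; three marker genes (ESR1, PGR, ERBB2)
#' drawn from a two-component mixture whose component is fixed by the
#' sample's planted receptor status (per-subtype positivity rates follow
#' the clinical pattern: subtype I ER-negative through subtype V uniformly
#' ER+/PR+/HER2-); a 13-gene recurrence-score panel co-expressed with the
#' markers and proliferation structure (high in subtypes I/II/IV, low in
#' V/VI); and exponential survival with subtype-by-regimen hazards
#' (subtype IV responds to CAF but not CMF; subtype V has a uniformly low
#' hazard insensitive to chemotherapy), censored uniformly over the
#' follow-up horizon.
#'
#' @param K number of subtypes (default 6).
#' @param nPerSubtype integer vector of per-subtype sample counts.
#' @param nCentroidProbes,nLinearProbes,nQuadraticProbes classifier probe
#'   block sizes (centroid + noise, linear in pivot 1, quadratic in
#'   pivot 2).
#' @param nNoiseProbes unstructured probes.
#' @param nPivotalGenes pivotal genes (anchors for probe selection).
#' @param tauCentroid SD of subtype mean shifts (log2), default 2.
#' @param sdProbeNoise,sdPivotNoise residual SDs (log2).
#' @param linearR,quadraticR2 target correlation strengths of the planted
#'   linear/quadratic blocks.
#' @param markerMeans,markerSd mixture component means (neg, pos) and
#'   common SD for the marker genes.
#' @param erPosProb,prPosProb,her2PosProb per-subtype positivity
#'   probabilities.
#' @param ihcErrorRate probability that a planted IHC label contradicts the
#'   expression-level truth (assay noise), default 0.03.
#' @param hazards K x 4 matrix of yearly event hazards, columns CMF, CAF,
#'   taxane, none.
#' @param regimenProb baseline regimen assignment probabilities (CMF, CAF,
#'   taxane, none).
#' @param horizonYears follow-up horizon; censoring times are uniform on
#'   (0, horizon).
#' @param seed integer seed (mandatory).
#' @return a list of class \code{SyntheticConfig}.
#' @export
syntheticConfig <- function(K = 6,
                            nPerSubtype = c(37, 34, 41, 81, 41, 93),
                            nCentroidProbes = 100,
                            nLinearProbes = 60,
                            nQuadraticProbes = 40,
                            nNoiseProbes = 700,
                            nPivotalGenes = 23,
                            tauCentroid = 2,
                            sdProbeNoise = 0.6,
                            sdPivotNoise = 0.3,
                            linearR = 0.85,
                            quadraticR2 = 0.8,
                            markerMeans = c(neg = 7, pos = 11),
                            markerSd = 0.5,
                            erPosProb = c(0, 0.03, 0.24, 0.86, 1, 0.88),
                            prPosProb = c(0.51, 0.41, 0.56, 0.90, 1, 0.95),
                            her2PosProb = c(0.11, 0.76, 0.44, 0.27, 0, 0.05),
                            ihcErrorRate = 0.03,
                            hazards = NULL,
                            regimenProb = c(CMF = 0.25, CAF = 0.3,
                                            taxane = 0.15, none = 0.3),
                            horizonYears = 15,
                            seed = 1L) {
  if (is.null(hazards)) {
    hazards <- rbind(
      I   = c(CMF = 0.05, CAF = 0.05, taxane = 0.05, none = 0.30),
      II  = c(CMF = 0.15, CAF = 0.12, taxane = 0.12, none = 0.35),
      III = c(CMF = 0.06, CAF = 0.06, taxane = 0.06, none = 0.10),
      IV  = c(CMF = 0.18, CAF = 0.04, taxane = 0.05, none = 0.25),
      V   = c(CMF = 0.02, CAF = 0.02, taxane = 0.02, none = 0.02),
      VI  = c(CMF = 0.06, CAF = 0.06, taxane = 0.06, none = 0.08))
  }
  cfg <- list(K = K, nPerSubtype = as.integer(nPerSubtype),
              nCentroidProbes = nCentroidProbes,
              nLinearProbes = nLinearProbes,
              nQuadraticProbes = nQuadraticProbes,
              nNoiseProbes = nNoiseProbes,
              nPivotalGenes = nPivotalGenes,
              tauCentroid = tauCentroid, sdProbeNoise = sdProbeNoise,
              sdPivotNoise = sdPivotNoise, linearR = linearR,
              quadraticR2 = quadraticR2, markerMeans = markerMeans,
              markerSd = markerSd, erPosProb = erPosProb,
              prPosProb = prPosProb, her2PosProb = her2PosProb,
              ihcErrorRate = ihcErrorRate, hazards = hazards,
              regimenProb = regimenProb, horizonYears = horizonYears,
              seed = as.integer(seed))
  .validateSyntheticConfig(cfg)
  structure(cfg, class = "SyntheticConfig")
}

.validateSyntheticConfig <- function(cfg) {
  if (length(cfg$nPerSubtype) != cfg$K)
    stop("nPerSubtype must have K entries")
  if (any(cfg$nPerSubtype < 0)) stop("counts must be non-negative")
  for (p in c("erPosProb", "prPosProb", "her2PosProb"))
    if (length(cfg[[p]]) != cfg$K)
      stop(p, " must have K entries")
  if (!all(dim(cfg$hazards) == c(cfg$K, 4)))
    stop("hazards must be a K x 4 matrix (CMF, CAF, taxane, none)")
  if (any(cfg$hazards <= 0)) stop("hazards must be positive")
  if (is.null(cfg$seed) || is.na(cfg$seed)) stop("seed is mandatory")
  invisible(cfg)
}

.rsPanelGenes <- setdiff(oncotypeGenes, c("HER2", "ER", "PGR"))

#' Generate a synthetic cohort with known truth
#'
#' Draws an expression matrix, a clinical table and the planted truth from
#' a [syntheticConfig()] recipe.  Fully reproducible: the same config
#' (including its seed) always yields identical output.
#'
#' The returned \code{SummarizedExperiment} carries the log2 expression in
#' assay \code{exprs}, the clinical table as \code{colData}, a probe
#' annotation (\code{block}) as \code{rowData}, and
#' \code{metadata(se)$truth} with: the planted subtype labels, the marker
#' status data.frame, the analytic marker cut-points implied by the
#' realized mixture weights, the planted probe blocks, and a good-prognosis
#' template (mean classifier-probe profile of the low-risk subtypes V/VI)
#' for the correlation risk score.
#'
#' @param cfg a [syntheticConfig()] list.
#' @param sampleSeed seed for the sample-level draws (noise, marker status,
#'   clinical covariates, survival).  The structural parameters -- pivot
#'   split patterns, probe anchors, slopes and baselines -- are always
#'   drawn from \code{cfg$seed}, so two calls with the same config but
#'   different \code{sampleSeed} yield independent cohorts from the same
#'   planted subtype recipe (e.g. a validation cohort for a fitted model).
#'   Defaults to \code{cfg$seed}.
#' @return a \code{SummarizedExperiment}; see Details.
#' @export
generateCohort <- function(cfg = syntheticConfig(), sampleSeed = NULL) {
  .validateSyntheticConfig(cfg)
  if (is.null(sampleSeed)) sampleSeed <- cfg$seed
  set.seed(cfg$seed)
  K <- cfg$K
  n <- sum(cfg$nPerSubtype)
  subtypeLabels <- as.character(utils::as.roman(seq_len(K)))
  subtype <- factor(rep(subtypeLabels, cfg$nPerSubtype),
                    levels = subtypeLabels)
  sampleIds <- sprintf("S%03d", seq_len(n))
  kIdx <- as.integer(subtype)

  ## --- pivotal genes: bimodal subtype split patterns -------------------
  ## Classifier-grade probes have flat/bimodal densities (low kurtosis), so
  ## pivotal genes carry balanced two-level subtype patterns (on/off across
  ## a split of the subtypes, like receptor biology) rather than arbitrary
  ## per-subtype means; pivotal gene 2 is three-level so that a block of
  ## probes can respond to it quadratically without degenerating.
  w <- cfg$nPerSubtype / n
  twoLevelSplit <- function() {
    repeat {
      mask <- rbinom(K, 1, 0.5) == 1
      wt <- sum(w[mask])
      if (any(mask) && any(!mask) && wt >= 0.25 && wt <= 0.75)
        return(ifelse(mask, 1, -1))
    }
  }
  # middle weight 0.3-0.5 and balanced outer levels keep the folded
  # (squared) response a well-balanced bimodal mixture
  threeLevelSplit <- function() {
    repeat {
      lev <- sample(c(-1, 0, 1), K, replace = TRUE)
      wts <- c(sum(w[lev == -1]), sum(w[lev == 0]), sum(w[lev == 1]))
      if (wts[2] >= 0.3 && wts[2] <= 0.5 &&
          all(wts[c(1, 3)] >= 0.2) && all(wts[c(1, 3)] <= 0.4))
        return(lev)
    }
  }
  ## structural draws (patterns, anchors, baselines): once per cfg$seed
  pivotNames <- sprintf("PIVOT_%02d", seq_len(cfg$nPivotalGenes))
  pivotPattern <- matrix(0, cfg$nPivotalGenes, K)
  pivotPattern[1, ] <- twoLevelSplit()
  if (cfg$nPivotalGenes >= 2) pivotPattern[2, ] <- threeLevelSplit()
  if (cfg$nPivotalGenes >= 3)
    for (r in 3:cfg$nPivotalGenes) pivotPattern[r, ] <- twoLevelSplit()
  pivotBase <- runif(cfg$nPivotalGenes, 8.5, 10.5)

  blockRows <- function(nr, prefix) {
    if (nr == 0) return(NULL)
    sprintf("%s_%03d", prefix, seq_len(nr))
  }
  linNames <- blockRows(cfg$nLinearProbes, "LIN")
  quadNames <- blockRows(cfg$nQuadraticProbes, "QUAD")
  centNames <- blockRows(cfg$nCentroidProbes, "CENT")
  noiseNames <- blockRows(cfg$nNoiseProbes, "NOISE")
  linSlope <- sample(c(-1, 1), cfg$nLinearProbes, replace = TRUE) *
    runif(cfg$nLinearProbes, 0.8, 1.2)
  linBase <- runif(cfg$nLinearProbes, 7, 10)
  quadGain <- sample(c(-1, 1), cfg$nQuadraticProbes, replace = TRUE) *
    runif(cfg$nQuadraticProbes, 0.8, 1.2)
  quadBase <- runif(cfg$nQuadraticProbes, 8, 10)
  twoLevelPivots <- setdiff(seq_len(cfg$nPivotalGenes), 2)
  centBase <- runif(cfg$nCentroidProbes, 8.5, 10.5)
  centAnchor <- sample(twoLevelPivots, cfg$nCentroidProbes, replace = TRUE)
  centSgn <- sample(c(-1, 1), cfg$nCentroidProbes, replace = TRUE)
  centJitter <- matrix(rnorm(cfg$nCentroidProbes * K, 0, 0.25),
                       cfg$nCentroidProbes, K)
  noiseBase <- runif(cfg$nNoiseProbes, 5, 12)

  ## sample-level draws: independent cohorts share the structure above
  set.seed(sampleSeed)
  pivots <- pivotBase + cfg$tauCentroid * pivotPattern[, kIdx] +
    matrix(rnorm(cfg$nPivotalGenes * n, 0, cfg$sdPivotNoise),
           cfg$nPivotalGenes, n)
  rownames(pivots) <- pivotNames

  # linear in pivotal gene 1: y = b x + base + e, e sized for target r
  p1 <- pivots[1, ]
  varP1 <- var(p1)
  sdLin <- sqrt(varP1 * (1 - cfg$linearR^2) / cfg$linearR^2)
  lin <- NULL
  if (cfg$nLinearProbes > 0) {
    lin <- linBase + outer(linSlope, p1 - mean(p1)) +
      matrix(rnorm(cfg$nLinearProbes * n, 0, sdLin) * abs(linSlope),
             cfg$nLinearProbes, n)
    rownames(lin) <- linNames
  }
  # symmetric nonlinear (folded / V-shaped) response to pivotal gene 2:
  # linear correlation vanishes by symmetry while the degree-2 fit captures
  # the shape, and the folded response stays cleanly bimodal (a literal
  # squared response is slightly leptokurtic and would trip the kurtosis
  # filter these probes are meant to pass)
  p2 <- pivots[2, ]
  q2 <- abs(p2 - pivotBase[2])
  varQ <- var(q2)
  sdQuad <- sqrt(varQ * (1 - cfg$quadraticR2) / cfg$quadraticR2)
  quad <- NULL
  if (cfg$nQuadraticProbes > 0) {
    quad <- quadBase + outer(quadGain, q2 - mean(q2)) +
      matrix(rnorm(cfg$nQuadraticProbes * n, 0, sdQuad) * abs(quadGain),
             cfg$nQuadraticProbes, n)
    rownames(quad) <- quadNames
  }
  # centroid probes: each anchored on a two-level pivot pattern with small
  # per-subtype jitter, so it is both subtype-informative and strongly
  # correlated with its anchor pivot
  cent <- NULL
  if (cfg$nCentroidProbes > 0) {
    shift <- centSgn * cfg$tauCentroid *
      pivotPattern[centAnchor, , drop = FALSE] + centJitter
    cent <- centBase + shift[, kIdx] +
      matrix(rnorm(cfg$nCentroidProbes * n, 0, cfg$sdProbeNoise),
             cfg$nCentroidProbes, n)
    rownames(cent) <- centNames
  }
  # unstructured noise probes
  noise <- NULL
  if (cfg$nNoiseProbes > 0) {
    noise <- noiseBase + matrix(rnorm(cfg$nNoiseProbes * n, 0, 0.8),
                                cfg$nNoiseProbes, n)
    rownames(noise) <- noiseNames
  }

  ## --- marker genes: status-driven bimodal mixtures -------------------
  drawStatus <- function(prob) {
    s <- rbinom(n, 1, prob[kIdx])
    factor(ifelse(s == 1, "pos", "neg"), levels = c("neg", "pos"))
  }
  erStatus <- drawStatus(cfg$erPosProb)
  prStatus <- drawStatus(cfg$prPosProb)
  her2Status <- drawStatus(cfg$her2PosProb)
  drawMarker <- function(status) {
    mu <- ifelse(status == "pos", cfg$markerMeans["pos"],
                 cfg$markerMeans["neg"])
    rnorm(n, mu, cfg$markerSd)
  }
  esr1 <- drawMarker(erStatus)
  pgr <- drawMarker(prStatus)
  erbb2 <- drawMarker(her2Status)
  markers <- rbind(ESR1 = esr1, PGR = pgr, ERBB2 = erbb2)

  ## --- recurrence-score panel ----------------------------------------
  # proliferation high in subtypes I/II/IV, low in V/VI
  prolifMu <- c(10.5, 10.5, 9, 10, 7.5, 8)[pmin(kIdx, 6)]
  panel <- rbind(
    GRB7 = 2 + 0.8 * erbb2 + rnorm(n, 0, 0.5),
    BCL2 = 2 + 0.6 * esr1 + rnorm(n, 0, 0.6),
    SCUBE2 = 2.5 + 0.6 * esr1 + rnorm(n, 0, 0.6),
    BIRC5 = prolifMu + rnorm(n, 0, 0.6),
    KI67 = prolifMu + rnorm(n, 0, 0.6),
    MYBL2 = prolifMu - 0.5 + rnorm(n, 0, 0.6),
    CCNB1 = prolifMu + 0.3 + rnorm(n, 0, 0.6),
    AURKA = prolifMu - 0.2 + rnorm(n, 0, 0.6),
    CTSL2 = c(9, 9.5, 9, 9.5, 8, 8.5)[pmin(kIdx, 6)] + rnorm(n, 0, 0.7),
    MMP11 = c(9.5, 9.5, 9, 9.5, 8, 8.5)[pmin(kIdx, 6)] + rnorm(n, 0, 0.7),
    CD68 = 9 + rnorm(n, 0, 0.5),
    GSTM1 = 5 + 0.3 * esr1 + rnorm(n, 0, 0.6),
    BAG1 = 6 + 0.3 * esr1 + rnorm(n, 0, 0.6))

  expr <- rbind(cent, lin, quad, pivots, markers, panel, noise)
  colnames(expr) <- sampleIds

  ## --- clinical covariates (stage/grade patterns by subtype) ----------
  age <- pmin(85, pmax(25, round(rnorm(n, 47, 9))))
  tProb <- cbind(c(8, 28, 1, 0), c(4, 23, 5, 2), c(10, 20, 7, 4),
                 c(16, 56, 5, 4), c(22, 17, 1, 1), c(41, 44, 7, 1))
  nProb <- cbind(c(20, 10, 4, 3), c(7, 10, 11, 6), c(16, 8, 11, 6),
                 c(31, 25, 14, 11), c(20, 12, 7, 2), c(43, 22, 16, 12))
  mProb <- c(1 / 37, 1 / 34, 1 / 41, 3 / 81, 0, 2 / 93)
  gProb <- cbind(c(1, 3, 30), c(0, 1, 28), c(2, 4, 33), c(2, 11, 62),
                 c(9, 18, 10), c(17, 38, 33))
  sampleCat <- function(probCol) {
    vapply(seq_len(n), function(i)
      sample.int(nrow(probCol), 1, prob = probCol[, kIdx[i]]), integer(1))
  }
  tStage <- sampleCat(tProb)
  nStage <- sampleCat(nProb) - 1L
  mStage <- rbinom(n, 1, mProb[kIdx])
  grade <- sampleCat(gProb)
  tnm <- ifelse(mStage == 1, "IV",
           ifelse(tStage == 1 & nStage == 0, "I",
             ifelse(tStage <= 2 & nStage <= 1, "II", "III")))

  regimens <- c("CMF", "CAF", "taxane", "none")
  regimen <- factor(regimens[vapply(seq_len(n), function(i)
    sample.int(4, 1, prob = cfg$regimenProb), integer(1))],
    levels = regimens)
  hormonal <- runif(n) < ifelse(erStatus == "pos", 0.85, 0.15)
  radiation <- runif(n) < 0.43

  ## --- survival: exponential with subtype x regimen hazard ------------
  hz <- cfg$hazards[cbind(kIdx, as.integer(regimen))]
  tEvent <- rexp(n, hz)
  cens <- runif(n, 0, cfg$horizonYears)
  mfsTime <- pmin(tEvent, cens)
  mfsEvent <- tEvent <= cens
  tDeath <- tEvent + rexp(n, 1 / 2)   # mean 2y from metastasis to death
  osTime <- pmin(tDeath, cens)
  osEvent <- tDeath <= cens

  # planted IHC: expression truth flipped at the assay error rate
  flip <- function(status) {
    out <- as.character(status)
    fl <- runif(n) < cfg$ihcErrorRate
    out[fl] <- ifelse(out[fl] == "pos", "neg", "pos")
    unk <- runif(n) < 0.05
    out[unk] <- "unknown"
    out
  }
  clinical <- data.frame(
    sample_id = sampleIds, age_years = age, t_stage = tStage,
    n_stage = nStage, m_stage = mStage, tnm_stage = tnm,
    nuclear_grade = grade,
    er_ihc = flip(erStatus), pr_ihc = flip(prStatus),
    her2_ihc = flip(her2Status),
    chemo_regimen = as.character(regimen),
    hormonal_rx = hormonal, radiation_rx = radiation,
    followup_years = osTime, dead_of_disease = osEvent,
    mfs_time_years = mfsTime, mfs_event = mfsEvent,
    os_time_years = osTime, os_event = osEvent,
    stringsAsFactors = FALSE)

  ## --- truth ----------------------------------------------------------
  analyticCut <- function(status) {
    wNeg <- mean(status == "neg")
    .posteriorEqualityCut(wNeg,
                          unname(cfg$markerMeans),
                          rep(cfg$markerSd, 2))
  }
  classifierNames <- c(centNames, linNames, quadNames)
  goodIdx <- kIdx >= K - 1          # last two subtypes: low-risk stratum
  template <- rowMeans(expr[classifierNames, goodIdx, drop = FALSE])
  truth <- list(
    subtype = setNames(subtype, sampleIds),
    markerStatus = data.frame(sample_id = sampleIds, ER = erStatus,
                              PR = prStatus, HER2 = her2Status,
                              stringsAsFactors = FALSE),
    cutpoints = c(ER = analyticCut(erStatus), PR = analyticCut(prStatus),
                  HER2 = analyticCut(her2Status)),
    classifierProbes = classifierNames,
    linearProbes = linNames, quadraticProbes = quadNames,
    pivotProbes = pivotNames,
    markerProbes = c(ER = "ESR1", PR = "PGR", HER2 = "ERBB2"),
    goodPrognosisTemplate = template)

  block <- rep(c("centroid", "linear", "quadratic", "pivot", "marker",
                 "rs_panel", "noise"),
               c(length(centNames), length(linNames), length(quadNames),
                 length(pivotNames), 3, nrow(panel),
                 length(noiseNames)))
  SummarizedExperiment(
    assays = list(exprs = expr),
    colData = S4Vectors::DataFrame(clinical, row.names = sampleIds),
    rowData = S4Vectors::DataFrame(block = block),
    metadata = list(truth = truth, config = cfg))
}

#' Planted truth of a synthetic cohort
#' @param se a \code{SummarizedExperiment} from [generateCohort()].
#' @return the truth list stored at generation time.
#' @export
cohortTruth <- function(se) {
  tr <- metadata(se)$truth
  if (is.null(tr)) stop("no planted truth in this object")
  tr
}

#' Simulate survival for one subtype/regimen stratum
#'
#' Draws event times from the configured exponential hazard of a given
#' subtype and regimen, censored uniformly over the follow-up horizon.
#' Used to study treatment contrasts (e.g. CAF vs CMF power within a
#' subtype) at chosen arm sizes.
#'
#' @param cfg a [syntheticConfig()].
#' @param subtype subtype label ("I".."VI") or index.
#' @param regimen one of "CMF", "CAF", "taxane", "none".
#' @param n number of patients.
#' @return data.frame with \code{time}, \code{event}.
#' @export
drawSurvivalTimes <- function(cfg, subtype, regimen, n) {
  .validateSyntheticConfig(cfg)
  if (is.character(subtype))
    subtype <- match(subtype, as.character(utils::as.roman(seq_len(cfg$K))))
  stopifnot(!is.na(subtype), subtype >= 1, subtype <= cfg$K)
  regimen <- match.arg(regimen, c("CMF", "CAF", "taxane", "none"))
  hz <- cfg$hazards[subtype, regimen]
  tEvent <- rexp(n, hz)
  cens <- runif(n, 0, cfg$horizonYears)
  data.frame(time = pmin(tEvent, cens), event = tEvent <= cens)
}

#' Recovery metrics of fitted results against planted truth
#'
#' Computes the adjusted Rand index between fitted and planted subtype
#' partitions, absolute cut-point errors, and marker call accuracy.
#'
#' @param truth truth list from [cohortTruth()].
#' @param labels fitted subtype labels, named by sample (optional).
#' @param cutpoints named numeric vector of fitted cut-points over any of
#'   ER/PR/HER2 (optional).
#' @param markerCalls data.frame with \code{sample_id} and any of
#'   \code{ER}/\code{PR}/\code{HER2} fitted calls (optional).
#' @return list with \code{ari}, \code{cutpointError},
#'   \code{markerAccuracy} (components present when inputs are).
#' @export
truthReport <- function(truth, labels = NULL, cutpoints = NULL,
                        markerCalls = NULL) {
  out <- list()
  if (!is.null(labels)) {
    if (is.null(names(labels)))
      stop("fitted labels must be named by sample")
    ids <- names(truth$subtype)
    if (!setequal(names(labels), ids))
      stop("sample sets of fitted labels and truth differ")
    labels <- labels[ids]
    out$ari <- mclust::adjustedRandIndex(as.character(truth$subtype),
                                         as.character(labels))
  }
  if (!is.null(cutpoints)) {
    shared <- intersect(names(cutpoints), names(truth$cutpoints))
    if (!length(shared)) stop("no cut-point roles shared with truth")
    out$cutpointError <- abs(cutpoints[shared] - truth$cutpoints[shared])
  }
  if (!is.null(markerCalls)) {
    if (!setequal(markerCalls$sample_id, truth$markerStatus$sample_id))
      stop("sample sets of marker calls and truth differ")
    idx <- match(truth$markerStatus$sample_id, markerCalls$sample_id)
    roles <- intersect(c("ER", "PR", "HER2"), colnames(markerCalls))
    out$markerAccuracy <- vapply(roles, function(r)
      mean(as.character(markerCalls[[r]][idx]) ==
             as.character(truth$markerStatus[[r]])), numeric(1))
  }
  out
}
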