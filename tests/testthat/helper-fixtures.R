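# Shared fixtures: a reduced synthetic cohort for fast unit tests and a
# tiny expression matrix builder.

smallCohortConfig <- function(seed = 101) {
  syntheticConfig(
    nPerSubtype = c(12, 11, 13, 26, 13, 30),
    nCentroidProbes = 40, nLinearProbes = 20, nQuadraticProbes = 15,
    nNoiseProbes = 150, nPivotalGenes = 8, seed = seed)
}

tinyExpr <- function(nr = 3, nc = 2, seed = 1) {
  set.seed(seed)
  matrix(round(runif(nr * nc, 4, 12), 3), nr, nc,
         dimnames = list(paste0("p", seq_len(nr)),
                         paste0("s", seq_len(nc))))
}

# minimal clinical table with nc samples
tinyClinical <- function(ids, followup = 5, dead = FALSE) {
  n <- length(ids)
  data.frame(
    sample_id = ids, age_years = 50, t_stage = 2L, n_stage = 0L,
    m_stage = 0L, tnm_stage = "II", nuclear_grade = 2L,
    er_ihc = "pos", pr_ihc = "pos", her2_ihc = "neg",
    chemo_regimen = "CAF", hormonal_rx = TRUE, radiation_rx = FALSE,
    followup_years = rep_len(followup, n),
    dead_of_disease = rep_len(dead, n),
    mfs_time_years = rep_len(followup, n), mfs_event = FALSE,
    os_time_years = rep_len(followup, n), os_event = FALSE,
    stringsAsFactors = FALSE)
}

allPassQC <- function(ids) {
  data.frame(sample_id = ids, rna_ok = TRUE, rna_sufficient = TRUE,
             array_ok = TRUE, stringsAsFactors = FALSE)
}
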