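# Shared setup for the analysis scripts: the showcase cohort at the
# study's conditions (90 AAL regions, 290 timepoints, TR 2 s, groups
# control/noHE/MHE/OHE of 35/17/9/9 subjects with a monotone disruption
# gradient). Scripts cache the generated cohort under scratch/ so the
# sequence 01 -> 06 reuses one draw; delete scratch/cohort.rds to redraw.

library(smallworldfc)

COHORT_SEED <- 42

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

load_cohort <- function() {
  cache <- file.path("scratch", "cohort.rds")
  if (file.exists(cache)) return(readRDS(cache))
  cohort <- generate_cohort(cohort_spec(seed = COHORT_SEED))
  saveRDS(cohort, cache)
  cohort
}

load_subject_matrices <- function(cohort) {
  cache <- file.path("scratch", "subject_matrices.rds")
  if (file.exists(cache)) return(readRDS(cache))
  mats <- lapply(cohort$timeseries, correlation_matrix)
  saveRDS(mats, cache)
  mats
}
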