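#!/usr/bin/env Rscript
# Temporal preprocessing demonstration on the cohort: linear detrend,
# regression of nine nuisance predictors (WM, CSF, global signal, six
# motion parameters), and 0.01-0.08 Hz zero-phase band-pass at TR = 2 s.
# The generator emits clean series, so drift, nuisance signals and
# high-frequency noise are injected here and then removed; the summary
# table records how much variance each stage removes and how well the
# cleaned series recover the clean-series correlation structure.

source(file.path("analysis", "00_common.R"))

cohort <- load_cohort()
tr <- cohort$spec$tr_seconds
nt <- cohort$spec$n_timepoints

set.seed(COHORT_SEED + 1)
ids <- cohort$subjects$subject_id[seq(1, 70, by = 10)]
rows <- list()
for (id in ids) {
  clean <- cohort$timeseries[[id]]
  t_ <- seq_len(nt)
  # drift + physiological nuisance + scanner noise, as preprocessing sees it
  nuis <- cbind(wm = rnorm(nt), csf = rnorm(nt), global = rnorm(nt),
                matrix(rnorm(nt * 6), nt, 6,
                       dimnames = list(NULL, paste0("motion", 1:6))))
  loading <- matrix(runif(9 * ncol(clean), 0.2, 0.6), 9)
  hf <- sin(2 * pi * 0.2 * t_ * tr)  # cardiac/respiratory-band component
  raw <- clean + outer(t_, runif(ncol(clean), -0.02, 0.02)) +
    nuis %*% loading + 0.5 * outer(hf, runif(ncol(clean), 0.5, 1))
  cleaned <- preprocess_roi(raw, nuisance = nuis, tr_seconds = tr)
  r_raw <- correlation_matrix(raw)
  r_clean <- correlation_matrix(clean)
  r_post <- correlation_matrix(cleaned)
  ut <- upper.tri(r_clean)
  rows[[id]] <- data.frame(
    subject_id = id,
    var_raw = mean(apply(raw, 2, var)),
    var_cleaned = mean(apply(cleaned, 2, var)),
    cor_recovery_raw = cor(r_raw[ut], r_clean[ut]),
    cor_recovery_cleaned = cor(r_post[ut], r_clean[ut]))
}
summary_tab <- do.call(rbind, rows)
write.csv(summary_tab, file.path("results", "preprocessing_summary.csv"),
          row.names = FALSE)
message("correlation-structure recovery (r with clean-series matrix):")
message(sprintf("  raw contaminated: %.3f   after preprocessing: %.3f",
                mean(summary_tab$cor_recovery_raw),
                mean(summary_tab$cor_recovery_cleaned)))
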