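#!/usr/bin/env Rscript
# Draw the synthetic resting-state cohort: 70 subjects in four groups
# (healthy controls and cirrhotic patients without HE, with minimal HE,
# and with overt HE), each with a 290 x 90 regional BOLD-like time-series
# matrix. Writes the subject table and cohort layout to results/, and the
# raw per-subject series as CSVs under scratch/cohort_csv/.

source(file.path("analysis", "00_common.R"))

cohort <- load_cohort()
spec <- cohort$spec

message(sprintf("cohort: %d subjects, %d regions, %d timepoints (TR %gs)",
                nrow(cohort$subjects), spec$n_regions, spec$n_timepoints,
                spec$tr_seconds))
print(table(cohort$subjects$group))
message("mean venous ammonia (mg/dL) by group:")
print(round(tapply(cohort$subjects$ammonia, cohort$subjects$group, mean,
                   na.rm = TRUE), 1))

write.csv(cohort$subjects, file.path("results", "subjects.csv"),
          row.names = FALSE)

layout <- c(list(seed = spec$seed, n_regions = spec$n_regions,
                 n_timepoints = spec$n_timepoints,
                 tr_seconds = spec$tr_seconds,
                 noise_sd = spec$noise_sd, delta_sd = spec$delta_sd,
                 base_homotopic_r = spec$base_homotopic_r,
                 base_distance_r = spec$base_distance_r,
                 base_background_r = spec$base_background_r,
                 base_within_module_r = spec$base_within_module_r),
            list(groups = spec$groups))
yaml::write_yaml(layout, file.path("results", "cohort_spec.yaml"))

csv_dir <- file.path("scratch", "cohort_csv")
dir.create(csv_dir, showWarnings = FALSE)
for (id in names(cohort$timeseries))
  write.csv(round(cohort$timeseries[[id]], 5),
            file.path(csv_dir, paste0(id, ".csv")), row.names = FALSE)
message("wrote per-subject series to ", csv_dir)
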