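#!/usr/bin/env Rscript
# Step 1 -- simulate the study cohort.
#
# No public intraoperative MAP/index dataset accompanies this analysis, so
# the cohort is synthetic: 91 patients at 20-s sampling, calibrated to a
# median of ~3 hypotensive events per patient and ~12% of monitored time
# spent below 65 mmHg, with intervention-like MAP jumps and an index signal
# that rises ahead of MAP declines. Ground truth is written alongside so
# later steps can be audited.

suppressPackageStartupMessages(library(hypoalert))

SEED <- 1014
dir.create("results", showWarnings = FALSE)

sim <- simulate_cohort(sim_config(n_patients = 91, seed = SEED))

write_vitals_csv(sim$cohort, "results/cohort_vitals.csv")
truth_events <- do.call(rbind, lapply(names(sim$truth), function(id) {
  ev <- sim$truth[[id]]$events
  if (nrow(ev) == 0) return(NULL)
  cbind(patient_id = id, ev)
}))
utils::write.csv(truth_events, "results/truth_events.csv", row.names = FALSE)
jsonlite::write_json(sim$calibration, "results/calibration.json",
                     auto_unbox = TRUE, digits = NA)

cal <- sim$calibration
cat(sprintf(paste0(
  "Simulated %d patients (seed %d): %d hypotensive events in total,\n",
  "median %.0f events/patient, %.1f%% of monitored time hypotensive,\n",
  "median cumulative hypotension %.1f min/patient.\n"),
  length(sim$cohort), SEED, cal$n_events_total,
  cal$median_events_per_patient, 100 * cal$hypo_time_fraction,
  cal$median_hypo_min))
cat("Wrote results/cohort_vitals.csv, results/truth_events.csv, results/calibration.json\n")
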