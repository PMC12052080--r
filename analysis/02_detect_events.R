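#!/usr/bin/env Rscript
# Step 2 -- detect hypotensive events, intervention artefacts and burden.
#
# Hypotension: MAP < 65 mmHg for at least one minute, until normalised for
# at least one minute. Interventions: abrupt MAP rises (>= 5 mmHg in 20 s or
# >= 8 mmHg in 2 min) from a baseline < 70 mmHg; alerts superseded by them
# are excluded downstream. Burden: area under the 65-mmHg threshold and its
# time-weighted average.

suppressPackageStartupMessages(library(hypoalert))

co <- read_vitals_csv("results/cohort_vitals.csv")

events <- lapply(co, detect_hypotension)
marks <- lapply(co, detect_interventions)
burden <- lapply(names(co), function(id)
  burden_summary(co[[id]], events[[id]]))
names(burden) <- names(co)

ev_tab <- do.call(rbind, lapply(names(co), function(id) {
  ev <- events[[id]]
  if (nrow(ev) == 0) return(NULL)
  cbind(patient_id = id, ev)
}))
mk_tab <- do.call(rbind, lapply(names(co), function(id) {
  mk <- marks[[id]]
  if (nrow(mk) == 0) return(NULL)
  cbind(patient_id = id, mk)
}))
bd_tab <- do.call(rbind, lapply(names(co), function(id)
  data.frame(patient_id = id, as.data.frame(burden[[id]]))))

utils::write.csv(ev_tab, "results/detected_events.csv", row.names = FALSE)
utils::write.csv(mk_tab, "results/intervention_marks.csv", row.names = FALSE)
utils::write.csv(bd_tab, "results/burden_per_patient.csv", row.names = FALSE)

n_ev <- vapply(events, nrow, integer(1))
hypo_min <- vapply(events, function(e) sum(e$duration) / 60, numeric(1))
aut <- bd_tab$aut_mmhg_min
twa <- bd_tab$twa_mmhg
q <- function(x) sprintf("%.1f [%.1f to %.1f]",
                         stats::median(x), stats::quantile(x, .25),
                         stats::quantile(x, .75))
cat(sprintf(paste0(
  "Detected %d events across %d patients (%d with >= 1 event);\n",
  "events/patient %s; cumulative hypotension (min) %s;\n",
  "area under threshold (mmHg min) %s; time-weighted average (mmHg) %s;\n",
  "%d intervention-like MAP rises marked.\n"),
  sum(n_ev), length(co), sum(n_ev > 0), q(n_ev), q(hypo_min), q(aut),
  sprintf("%.2f [%.2f to %.2f]", stats::median(twa),
          stats::quantile(twa, .25), stats::quantile(twa, .75)),
  sum(vapply(marks, nrow, integer(1)))))
cat("Wrote results/detected_events.csv, results/intervention_marks.csv, results/burden_per_patient.csv\n")
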