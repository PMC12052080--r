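#!/usr/bin/env Rscript
# Step 6 -- figures.
#
# (a) per-predictor bars: percentage of hypotensive events preceded by an
#     alert, alongside the positive predictive value;
# (b) MAP spread (median, IQR, min-max) at each index value.

suppressPackageStartupMessages(library(hypoalert))

SEED <- 1014
co <- read_vitals_csv("results/cohort_vitals.csv")
bundle <- run_evaluation(
  co, battery = default_battery(), schemes = "adjacency",
  boot = bootstrap_config(iterations = 200, seed = SEED))
files <- make_figures(bundle, "results/figures")
cat("Wrote:", paste(files, collapse = ", "), "\n")
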