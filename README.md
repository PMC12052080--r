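# hypoalert

Evaluation of intraoperative hypotension alert predictors on 20-second
mean arterial pressure (MAP) time series.

## The problem

Commercial monitors raise alerts intended to warn anaesthesiologists of
impending intraoperative hypotension — either from a proprietary 0–100
hypotension index (an audible alert at index ≥ 85, and a treatment-popup
when the exceedance is sustained for 40 s) or from plain MAP lower-limit
alarms. Whether the index buys clinically meaningful warning time over a
simple MAP threshold in the 70–75 mmHg range is contested, as is the use of
AUC-style validation for alerts whose clinical appearance is a threshold
crossing. `hypoalert` implements an evaluation framework built on three
clinically interpretable metrics instead:

* **time-to-event (TTE)** — minutes from alert-episode start to the onset of
  the matched hypotensive event (MAP < 65 mmHg lasting ≥ 1 min, ended only
  by ≥ 1 min of normalisation);
* **positive predictive value (PPV)** — the share of alert episodes followed
  by hypotension, `100·TP/(TP+FP)`;
* **missed-event rate** — the per-patient proportion of hypotensive events
  not preceded by a qualifying alert.

Alerts are classified **adjacency-oriented** (a true positive must stay
active until onset) or **timeframe-oriented** (any onset within 20 min of
alert start counts). Alert episodes superseded by a detected
blood-pressure-raising intervention (a rise ≥ 5 mmHg in 20 s or ≥ 8 mmHg in
2 min from a baseline < 70 mmHg) are excluded from the counts. Besides
index- and MAP-threshold alerts, the battery includes the linear
extrapolation predictor

```
LepMAP0(t) = 2·MAP(t−n) − MAP(t−2n)          n ∈ {1, 2, 5} min
```

which alerts when the extrapolated MAP falls below 65 mmHg, plus a
shift-loop time-to-event extension that walks the two source samples
backwards in 20-s steps for as long as the extended extrapolation still
predicts hypotension. Point estimates carry 95% confidence intervals from a
2000-iteration bootstrap that resamples **patients** with replacement, and
predictors are compared by paired per-event time gains (a missed event
contributes a lead time of zero).

No patient-level dataset is shipped; a calibrated synthetic-cohort
generator (`simulate_cohort()`) reproduces the statistical shape of an
intraoperative cohort — ~3.6-h procedures, a median of 3 hypotensive events
per patient, ~12% of monitored time hypotensive, intervention-like MAP
jumps, and an index that rises ahead of MAP declines — so the entire
pipeline is testable end to end.

## Worked example

```r
library(hypoalert)

sim <- simulate_cohort(sim_config(n_patients = 91, seed = 1014))
sim$calibration[c("median_events_per_patient", "hypo_time_fraction")]
#> $median_events_per_patient
#> [1] 3
#> $hypo_time_fraction
#> [1] 0.118...

b <- run_evaluation(sim$cohort,
                    battery = default_battery(),
                    schemes = "adjacency",
                    boot    = bootstrap_config(2000, seed = 1014))
subset(b$metrics, predictor_id %in% c("HPI-85-popup", "MAP-70", "40sec-MAP-70"),
       select = c(predictor_id, tte_min, ppv, missed_pct, npv))
#>   predictor_id  tte_min      ppv missed_pct      npv
#>   HPI-85-popup     3.28    28.4        0.0     96.6
#>   MAP-70           2.69    24.9        0.0     99.8
#>   40sec-MAP-70     2.70    39.8        0.0     99.6
```

Read: on this synthetic cohort the index popup alert leads hypotension by
about 3.3 min on correctly predicted events versus 2.7 min for a MAP-70
alarm (the paired gain, `b$gains`, is ≈ +0.23 min in the popup's favour);
adding the 40-s time-dependence to the MAP-70 alarm leaves its lead time
unchanged but removes brief noise-driven exceedances, raising PPV from ~25%
to ~40%; and essentially no events are missed by either. The instant
extrapolation predictors (`LepMAP0-*`) miss the majority of events — on a
near-linear decline the extrapolation equals the current MAP, which is
still ≥ 65 mmHg just before onset.

The numbered scripts under `analysis/` run this as a narrative workflow
(simulate → detect → classify → summarise → index/MAP relation → figures),
writing tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_detect_events.R
Rscript analysis/03_evaluate_alerts.R
Rscript analysis/04_outcome_table.R
Rscript analysis/05_index_map_relation.R
Rscript analysis/06_figures.R
```

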