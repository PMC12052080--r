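---
title: "Evaluating hypotension alert predictors: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating hypotension alert predictors: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypoalert)
```

This vignette documents the models and conventions behind `hypoalert`: how
events, interventions and alert episodes are defined on 20-s-sampled MAP
series, how alerts are scored, how uncertainty is quantified, what the
synthetic cohort emulates, and which design choices were genuinely open.

## Data model and time conventions

A `vitals_series` holds one patient's MAP samples (mmHg) at a nominal 20-s
interval (0.05 Hz), optionally with a concurrent 0--100 hypotension-index
value. Monitors deliver one averaged value per 20-s interval; we timestamp
each sample at the start of the interval it represents, so a sample at time
$t$ covers $[t, t+20)$ seconds. All durations below follow from this
forward-coverage convention: a run of $k$ consecutive samples covers $20k$
seconds, an alert episode's `end_t` is its last qualifying sample plus
20 s, and three consecutive sub-threshold samples are the minimal span
reaching one minute.

Sampling gaps longer than 20 s are recorded explicitly. Gaps longer than
60 s split a series into independent evaluation segments: the original
study is silent on monitoring dropouts, and refusing to let an event,
normalisation period or alert episode span unobserved time avoids
fabricating adjacency across missing data. Time is seconds internally;
reports convert to minutes.

## Events, interventions, burden

**Hypotension** is MAP < 65 mmHg lasting at least one minute, terminated
only once MAP has normalised ($\ge$ 65 mmHg) for at least one minute.
Operationally: maximal sub-threshold runs; two runs separated by *less*
than 60 s of normalisation merge (a gap of exactly 60 s separates — "at
least one minute" is inclusive); merged groups with under 60 s of total
sub-threshold coverage are discarded. The detector is validated against a
brute-force interval-enumeration oracle on thousands of random traces,
including the 40-s/60-s merge boundary.

**Interventions.** Without treatment annotations, blood-pressure-raising
therapy is inferred from its haemodynamic signature: a rise of
$\ge$ 5 mmHg between consecutive samples, or $\ge$ 8 mmHg net across any
window of at most 2 min, starting from a baseline sample below 70 mmHg.
The 2-min criterion is read as the *net* rise over the window with the
baseline taken at the window start — the plainest reading of the printed
rule; a max-minus-min reading would fire on oscillations that never
sustain a rise. Overlapping raw detections collapse transitively to one
mark at the earliest completion time (ties: the 20-s rule first, then the
largest rise). Alert episodes containing a mark are excluded from
true/false-positive counting; how long after a mark an alert remains
"superseded" is genuinely undefined, so the post-episode grace window
defaults to 0 s and is configurable.

**Burden.** The area under the 65-mmHg threshold is the rectangle-rule sum
$\sum (65 - \mathrm{MAP}_i) \cdot 20/60$ over sub-threshold samples
(mmHg·min); the time-weighted average divides by monitored minutes.

## Alert definitions

A predictor is a signal, a threshold, and an optional 40-s
time-dependence:

* index alerts qualify at index $\ge$ 85; MAP alerts at MAP below a
  threshold in 70--75 mmHg; extrapolation alerts at a predicted MAP below
  65 mmHg;
* "sustained for 40 s" at 20-s averaged sampling means **two** consecutive
  qualifying samples (2 × 20 s of coverage). Three samples would demand
  60 s; the device's true popup cadence is not published, so the weaker
  reading is used and is stated here rather than buried in code;
* samples inside ongoing hypotensive events are masked from episode
  construction — predicting an event already underway is meaningless — and
  an episode interrupted by an event restarts after it;
* time-to-event is measured from the episode's **first** qualifying sample
  (`start_t`), not from the moment the 40-s criterion completes. This is
  the only reading consistent with a sustained alert showing a *longer*
  lead time than its instant counterpart, as observed in practice: the
  40-s filter drops short-lived episodes (a selection effect on episode
  duration) without delaying the clock on surviving ones.

**Linear extrapolation (LepMAP0).** The prediction for target time $t$ is
$2\,\mathrm{MAP}(t-n) - \mathrm{MAP}(t-2n)$, the line through the two
source samples extended $n$ forward. Predictions are indexed at their
target time, so an instant extrapolation alert qualifies at the sample
whose predicted value crosses 65 mmHg. Its intrinsic lead time is fixed at
$n$; the **time-to-event extension** therefore shifts both source samples
back in 20-s steps $x$ and extends the line $h = n + x$ forward:
$\widehat{\mathrm{MAP}} = \mathrm{MAP}(o-h) + \frac{h}{n}\left(\mathrm{MAP}(o-h) - \mathrm{MAP}(o-h-n)\right)$
for onset $o$. The extension grows while every extrapolation stays below
65 mmHg and stops at the first failure, missing history, or 20 min; the
loop semantics (not a closed form) are normative, and the implementation
is tested against a literal replay. The precondition is a correct base
prediction at the onset; otherwise the event counts as missed.

## Classification schemes

**Adjacency-oriented** (primary): an episode is a true positive only if it
activates before and remains active until onset — its coverage must reach
the sample immediately preceding the onset, with zero tolerated gap
(configurable). Each event matches at most one episode (earliest start).
Non-alert periods (record span minus episodes minus events, per segment)
are false negatives when they directly precede an onset, else true
negatives.

**Timeframe-oriented**: an episode is a true positive if any onset falls
in the half-open window $(\mathrm{start}, \mathrm{start} + 20\,\mathrm{min}]$
— an onset exactly at alert start is not a prediction. Every such episode
counts as TP (this is what makes the adjacency TP set a subset of the
timeframe TP set, a property we test); per-event accounting uses a
*primary* match, the earliest-starting TP episode for that event. A
non-alert period followed by an onset within the window is a false
negative only when no alert starts in between; otherwise it is discarded
rather than counted — the alert that did appear provides the prediction.

Both schemes conserve episodes exactly:
$\mathrm{TP} + \mathrm{FP} + \mathrm{EXCLUDED} = \#\text{episodes}$.

## Metrics and uncertainty

Point estimates pool counts over the cohort. Time-to-event averages over
correctly predicted events only; paired comparisons cover **all** events,
with a missed event contributing a lead time of zero (so "A leads by 2 min,
B misses" is a 2-min gain). The missed-event rate aggregates per-patient
proportions (patients without events are excluded from its denominator);
because the field reports both phrasings, the median and the mean of the
per-patient proportions are both emitted.

Confidence intervals come from a percentile bootstrap (default 2000
iterations) resampling **patients** with replacement — the unit that
respects within-patient correlation of alerts and events; the reported
centre is the bootstrap mean, alongside the pooled point estimate, since
published tables do not always say which is shown. The bootstrap is
bit-reproducible given its seed, degenerate cohorts of identical patients
yield zero-width intervals, and interval widths scale as
$1/\sqrt{\text{patients}}$ on synthetic cohorts (both tested).

With zero alerts the PPV is reported as not available, never as 0.

## The synthetic cohort

The generator exists to make every pipeline stage testable without any
patient data; its defaults are the study conditions and are not adjusted
per analysis.

* **Durations** log-normal, median 3.6 h (`sdlog` 0.39, floor 30 min),
  matching a typical elective non-cardiac-surgery case mix.
* **Baseline MAP** per patient $\sim N(80, 4)$ mmHg (floored at 75 so the
  drift cannot graze the hypotension threshold on its own), with a slow
  mean-reverting Ornstein--Uhlenbeck drift (relaxation time 10 min,
  stationary SD 3 mmHg) and white measurement noise (SD 1 mmHg).
* **Events**: counts negative-binomial (mean 6, size 1.4 — median 3 after
  placement constraints); each event is a descent ramp (2--6 min) to just
  above 70 mmHg, a short sub-70 plateau (~67.5 mmHg, 5--9 samples), a
  sub-65 lobe (log-normal width, depth 5--12 mmHg below threshold), and a
  deliberately *slow* spontaneous recovery (0.8 mmHg per sample while
  below 72 mmHg) so that natural normalisation never mimics a treatment to
  the rise detector. The jointly chosen count and width defaults put
  hypotension at roughly 12% of monitored time.
* **Near-miss dips** (Poisson, mean 5/patient) descend to 67--75 mmHg and
  recover the same slow way; they are what give threshold alerts their
  false positives.
* **Interventions** truncate ~35% of event lobes (and occasionally deep
  near-misses) with an upward jump of 6--15 mmHg in one sample, recorded
  as ground truth.
* **Index**: $100 \cdot \mathrm{logistic}(-3.2 + 0.9\,(75 - \mathrm{MAP})
  + 0.9 \cdot (-\text{slope}_{2\,\mathrm{min}}))$ plus $N(0, 3)$ noise,
  clipped and rounded to 0--100. Level and short-horizon decline jointly
  drive the index above 85 on the pre-onset plateau and during steep
  descents — anticipatory, strongly rank-anti-correlated with MAP
  ($\rho < -0.5$ by default, tunable toward 0 by raising the index noise)
  — without claiming to reproduce any proprietary algorithm.
* **Ground truth** is the event definition applied to the noise-free path,
  so truth satisfies the event rules by construction; the detector on the
  noisy trace recovers ≥ 95% of onsets within one sample.
* All randomness derives from one master seed via per-patient seeds, so
  cohorts are reproducible patient by patient.

What the synthetic cohort does **not** emulate: beat-to-beat waveform
structure, drug pharmacology, autocorrelated measurement artefacts, and —
importantly — the irregular, non-monotone character of real pre-hypotension
MAP trajectories. Its descents are smooth by design, which flatters
trend-following predictors: the 2-min linear extrapolation, for example,
misses far fewer events here than it would on real data. Passing the
directional tests therefore shows the *machinery* ranks predictors the way
the clinical data did, not that the synthetic effect sizes equal clinical
ones.

## Numerical choices and degenerate inputs

Interval comparisons use a 1e-9 tolerance on the seconds scale; quantiles
are type-7; Spearman's $\rho$ uses mid-ranks for ties and is reported as
not available below 3 pairs. The intervention-outlier window around a mark
for the index--MAP analyses is ±120 s (the long-rule window), configurable.
Episodes still active at a record or segment end are flagged censored but
participate normally in classification. Empty inputs (no alerts, no
events, patients without events) propagate as not-available values rather
than zeros wherever a rate would otherwise be fabricated.

## Problem sizes used in the checks

The test suite validates the event detector against its enumeration oracle
on 1000 random 30-sample traces, the structural monotonicities on 200
simulated patients, the directional cohort findings on a 91-patient
default cohort, and the bootstrap scaling on cohorts of 10/40/160 patients
at 500 iterations averaged over five replicates per size; the analysis
scripts and the acceptance script use the full 91-patient cohort with
2000-iteration bootstraps. These sizes keep each property statistically
decidable while the whole suite runs in a couple of minutes.

## Known limitations

* The intervention detector is heuristic and type-blind; missed
  treatments inflate false positives and falsely detected ones erode true
  negatives, exactly as in the study this framework re-implements.
* The 40-s popup cadence (2 vs 3 samples) and the popup's time-to-event
  anchor are inferences from published behaviour, stated above.
* NPV depends on how non-alert periods are delimited (maximal periods
  here); published 100% NPVs are compatible with several delimitations.
* Supplementary-level analyses (harmonised 40-s definitions, timeframe
  variants) are available through the same API but are exercised mainly on
  synthetic data.
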