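#' Detect hypotensive events
#'
#' Hypotension is a run of MAP below 65 mmHg lasting at least one minute,
#' terminated only once MAP has normalised (>= 65 mmHg) for at least one
#' minute. At 20-s sampling this means: maximal runs of sub-threshold
#' samples, two runs separated by less than 60 s of normalised coverage are
#' merged into one event, and merged groups whose total sub-threshold
#' coverage is below 60 s are not events. A normalisation gap of exactly
#' 60 s terminates an event.
#'
#' Runs never extend across sampling gaps (> 20 s) or across segment breaks;
#' time between runs is counted as elapsed non-hypotensive time, so a 40-s
#' recording gap inside an episode behaves like 40 s of normalisation.
#'
#' @param series A [vitals_series()].
#' @param threshold Hypotension threshold in mmHg (default 65).
#' @param min_event_s Minimum total sub-threshold coverage (default 60 s).
#' @param min_norm_s Normalisation time that terminates an event (default 60 s).
#' @return Data frame, one row per event ordered by onset: `onset_t` (time of
#'   first sub-threshold sample), `end_t` (last sub-threshold sample + 20 s
#'   coverage), `duration` (`end_t - onset_t`, seconds), `n_sub` (number of
#'   sub-threshold samples), `sub_time_s` (their total coverage).
#' @export
detect_hypotension <- function(series, threshold = 65, min_event_s = 60,
                               min_norm_s = 60) {
  t <- series$t; map <- series$map
  empty <- data.frame(onset_t = numeric(), end_t = numeric(),
                      duration = numeric(), n_sub = integer(),
                      sub_time_s = numeric())
  n <- length(t)
  if (n == 0L) return(empty)
  sub <- map < threshold
  brk <- diff(t) > DT + EPS  # gap or segment change breaks a run
  runs <- true_runs(sub, brk)
  if (nrow(runs) == 0L) return(empty)

  # Merge consecutive runs separated by < min_norm_s of normalised time,
  # but never across a segment boundary (gaps > 60 s split by construction).
  grp <- integer(nrow(runs)); grp[1L] <- 1L
  if (nrow(runs) > 1L) {
    for (k in 2:nrow(runs)) {
      gap_s <- t[runs$start[k]] - (t[runs$end[k - 1L]] + DT)
      same_seg <- series$segment[runs$start[k]] == series$segment[runs$end[k - 1L]]
      grp[k] <- if (same_seg && gap_s < min_norm_s - EPS) grp[k - 1L] else grp[k - 1L] + 1L
    }
  }
  ev <- do.call(rbind, lapply(split(seq_len(nrow(runs)), grp), function(ks) {
    n_sub <- sum(runs$end[ks] - runs$start[ks] + 1L)
    data.frame(onset_t = t[runs$start[ks[1L]]],
               end_t = t[runs$end[ks[length(ks)]]] + DT,
               n_sub = as.integer(n_sub),
               sub_time_s = n_sub * DT)
  }))
  ev <- ev[ev$sub_time_s >= min_event_s - EPS, , drop = FALSE]
  if (nrow(ev) == 0L) return(empty)
  ev$duration <- ev$end_t - ev$onset_t
  rownames(ev) <- NULL
  ev[, c("onset_t", "end_t", "duration", "n_sub", "sub_time_s")]
}

#' Detect blood-pressure-raising intervention artefacts
#'
#' Marks abrupt MAP increases consistent with a haemodynamic intervention:
#' a rise of at least 5 mmHg between consecutive samples (the 20-s rule) or
#' of at least 8 mmHg across any window of at most 2 min (the 2-min rule,
#' net rise over the window), in both cases starting from a baseline sample
#' below 70 mmHg. Raw detections whose windows overlap collapse transitively
#' to a single mark at the earliest completion time (ties: 20-s rule first,
#' then the largest rise).
#'
#' @param series A [vitals_series()].
#' @param short_delta Minimum consecutive-sample rise (default 5 mmHg).
#' @param long_delta Minimum rise within the long window (default 8 mmHg).
#' @param long_window_s Long-rule window length (default 120 s).
#' @param baseline_max Baseline gate: window-start MAP must be below this
#'   (default 70 mmHg).
#' @return Data frame, one row per mark: `t` (completion time), `rule`
#'   (`"short"` or `"long"`), `delta` (mmHg rise), `baseline` (window-start
#'   MAP), `window_start` (window-start time).
#' @export
detect_interventions <- function(series, short_delta = 5, long_delta = 8,
                                 long_window_s = 120, baseline_max = 70) {
  t <- series$t; map <- series$map; seg <- series$segment
  n <- length(t)
  empty <- data.frame(t = numeric(), rule = character(), delta = numeric(),
                      baseline = numeric(), window_start = numeric())
  if (n < 2L) return(empty)
  det <- list()
  for (j in 2:n) {
    i <- j - 1L
    while (i >= 1L && seg[i] == seg[j] && t[j] - t[i] <= long_window_s + EPS) {
      delta <- map[j] - map[i]
      if (map[i] < baseline_max - EPS) {
        if (i == j - 1L && t[j] - t[i] <= DT + EPS && delta >= short_delta - EPS) {
          det[[length(det) + 1L]] <- data.frame(
            t = t[j], rule = "short", delta = delta,
            baseline = map[i], window_start = t[i])
        } else if (delta >= long_delta - EPS) {
          det[[length(det) + 1L]] <- data.frame(
            t = t[j], rule = "long", delta = delta,
            baseline = map[i], window_start = t[i])
        }
      }
      i <- i - 1L
    }
  }
  if (length(det) == 0L) return(empty)
  det <- do.call(rbind, det)
  collapse_interventions(det)
}

# Transitive overlap clustering of raw detections; one mark per cluster at
# the earliest completion time (tie-break: short rule, then largest delta).
collapse_interventions <- function(det) {
  det <- det[order(det$window_start, det$t), , drop = FALSE]
  cl <- integer(nrow(det)); cl[1L] <- 1L
  max_end <- det$t[1L]
  if (nrow(det) > 1L) {
    for (k in 2:nrow(det)) {
      if (det$window_start[k] < max_end - EPS) cl[k] <- cl[k - 1L]
      else cl[k] <- cl[k - 1L] + 1L
      max_end <- max(max_end, det$t[k])
    }
  }
  out <- do.call(rbind, lapply(split(det, cl), function(d) {
    d <- d[order(d$t, d$rule != "short", -d$delta), , drop = FALSE]
    d[1L, , drop = FALSE]
  }))
  rownames(out) <- NULL
  out[order(out$t), , drop = FALSE]
}

#' Summarise hypotension burden
#'
#' Area under the 65-mmHg threshold (AUT, mmHg min) is the rectangle-rule sum
#' over all sub-threshold samples of `(65 - MAP) * 20/60`; its time-weighted
#' average (TWA, mmHg) divides by the monitored time. Total hypotensive time
#' is the summed duration of the detected events.
#'
#' @param series A [vitals_series()].
#' @param events Output of [detect_hypotension()] on the same series.
#' @param threshold Threshold in mmHg (default 65).
#' @return List with `n_events`, `total_hypo_time_min`, `aut_mmhg_min`,
#'   `twa_mmhg` and `monitored_min`.
#' @export
burden_summary <- function(series, events, threshold = 65) {
  if (nrow(events) > 0L) {
    on_idx <- match(events$onset_t, series$t)
    if (anyNA(on_idx) || any(series$map[on_idx] >= threshold))
      integrity_error("events are not consistent with the series")
  }
  sub <- series$map < threshold
  aut <- sum((threshold - series$map[sub]) * DT / 60)
  mon <- monitored_minutes(series)
  list(n_events = nrow(events),
       total_hypo_time_min = sum(events$duration) / 60,
       aut_mmhg_min = aut,
       twa_mmhg = if (mon > 0) aut / mon else 0,
       monitored_min = mon)
}
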