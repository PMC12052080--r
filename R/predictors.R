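#' Define an alert predictor
#'
#' An alert definition names a signal and the rule that makes a sample
#' "qualifying": the hypotension index alerts when it is at or above its
#' threshold; MAP and the LepMAP0 extrapolation alert when the signal falls
#' below the threshold. `min_duration = 40` adds the 40-s time-dependence
#' (the condition must persist for two consecutive 20-s samples before the
#' alert counts), mirroring the popup behaviour of the index monitor.
#'
#' @param predictor_id Label used in reports.
#' @param signal One of `"HPI"`, `"MAP"`, `"LEPMAP0"`.
#' @param threshold Index units for HPI (in `[0, 100]`); mmHg otherwise
#'   (in `(0, 200)`). LepMAP0 conventionally uses 65 (a hypotension
#'   prediction).
#' @param min_duration `0` (instant) or `40` seconds.
#' @param horizon_n Extrapolation interval n in seconds, LepMAP0 only
#'   (60, 120 or 300 in the default battery; any positive multiple of 20).
#' @return Object of class `alert_definition`.
#' @export
alert_definition <- function(predictor_id, signal = c("MAP", "HPI", "LEPMAP0"),
                             threshold, min_duration = 0, horizon_n = NULL) {
  signal <- match.arg(signal)
  if (!min_duration %in% c(0, 40))
    config_error("min_duration must be 0 or 40 seconds")
  if (signal == "HPI" && (threshold < 0 || threshold > 100))
    config_error("HPI threshold must lie in [0, 100]")
  if (signal != "HPI" && (threshold <= 0 || threshold >= 200))
    config_error("MAP/LepMAP0 threshold must lie in (0, 200)")
  if (signal == "LEPMAP0") {
    if (is.null(horizon_n)) config_error("LepMAP0 definitions require horizon_n")
    if (horizon_n <= 0 || horizon_n %% DT != 0)
      config_error("horizon_n must be a positive multiple of the 20-s sampling interval")
  } else if (!is.null(horizon_n)) {
    config_error("horizon_n is only meaningful for LEPMAP0 definitions")
  }
  structure(list(predictor_id = predictor_id, signal = signal,
                 threshold = threshold, min_duration = min_duration,
                 horizon_n = horizon_n),
            class = "alert_definition")
}

#' Default predictor battery
#'
#' The comparison set evaluated throughout: index alerts at 85 (instant and
#' 40-s popup), every MAP threshold from 70 to 75 mmHg (instant and with the
#' 40-s time-dependence), and LepMAP0 at 1, 2 and 5 min extrapolation
#' horizons (instant and 40-s variants), alerting on predicted MAP below
#' 65 mmHg.
#'
#' @return Named list of [alert_definition()]s (20 predictors).
#' @export
default_battery <- function() {
  defs <- list(
    alert_definition("HPI-85", "HPI", 85, 0),
    alert_definition("HPI-85-popup", "HPI", 85, 40))
  for (thr in 70:75) {
    defs <- c(defs, list(
      alert_definition(sprintf("MAP-%d", thr), "MAP", thr, 0),
      alert_definition(sprintf("40sec-MAP-%d", thr), "MAP", thr, 40)))
  }
  for (nm in c(1, 2, 5)) {
    defs <- c(defs, list(
      alert_definition(sprintf("LepMAP0-%dmin", nm), "LEPMAP0", 65, 0, nm * 60),
      alert_definition(sprintf("LepMAP0-%dmin-40s", nm), "LEPMAP0", 65, 40, nm * 60)))
  }
  names(defs) <- vapply(defs, `[[`, character(1), "predictor_id")
  defs
}

# Per-sample qualifying indicator for a definition (NA where undefined).
alert_qualifying <- function(series, defn) {
  switch(defn$signal,
    MAP = series$map < defn$threshold,
    HPI = {
      if (!has_hpi(series))
        capability_error(sprintf(
          "predictor '%s' requires an index signal the series lacks",
          defn$predictor_id))
      series$hpi >= defn$threshold
    },
    LEPMAP0 = {
      lep <- lepmap0_series(series, defn$horizon_n)
      v <- rep(NA_real_, n_samples(series))
      v[match(lep$target_t, series$t)] <- lep$value
      v < defn$threshold
    })
}

#' Construct alert episodes for a predictor
#'
#' An alert episode is a maximal run of qualifying samples, evaluated per
#' segment and outside the masked intervals (normally the ongoing
#' hypotensive events: an alert cannot "predict" an event already underway,
#' so episodes are interrupted by the mask and restart after it). Runs whose
#' coverage is shorter than `min_duration` are discarded.
#'
#' @param series A [vitals_series()].
#' @param defn An [alert_definition()].
#' @param mask Optional data frame of closed-open intervals `start`/`end`
#'   (seconds) whose samples are ignored; pass the event spans from
#'   [detect_hypotension()] via [event_mask()].
#' @return Data frame of episodes: `predictor_id`, `start_t` (first
#'   qualifying sample), `qualify_t` (time the duration criterion is met:
#'   `start_t` when instant, the second consecutive sample when
#'   `min_duration = 40`), `end_t` (last qualifying sample + 20-s coverage),
#'   `censored` (still active at the record or segment end), `n_samples`.
#' @export
threshold_episodes <- function(series, defn, mask = NULL) {
  qual <- alert_qualifying(series, defn)
  qual[is.na(qual)] <- FALSE
  t <- series$t
  if (!is.null(mask) && nrow(mask) > 0L) {
    for (k in seq_len(nrow(mask)))
      qual[t >= mask$start[k] - EPS & t < mask$end[k] - EPS] <- FALSE
  }
  brk <- diff(t) > DT + EPS
  runs <- true_runs(qual, brk)
  min_len <- max(1L, as.integer(ceiling(defn$min_duration / DT)))
  runs <- runs[(runs$end - runs$start + 1L) >= min_len, , drop = FALSE]
  seg_last <- rev(seq_along(t))[!duplicated(rev(series$segment))]  # last index per segment
  data.frame(
    predictor_id = rep(defn$predictor_id, nrow(runs)),
    start_t = t[runs$start],
    qualify_t = if (min_len > 1L) t[runs$start + min_len - 1L] else t[runs$start],
    end_t = t[runs$end] + DT,
    censored = runs$end %in% seg_last,
    n_samples = runs$end - runs$start + 1L)
}

#' Event spans as an episode-construction mask
#'
#' @param events Output of [detect_hypotension()].
#' @return Data frame of closed-open `start`/`end` intervals.
#' @export
event_mask <- function(events) {
  if (is.null(events) || nrow(events) == 0L)
    return(data.frame(start = numeric(), end = numeric()))
  data.frame(start = events$onset_t, end = events$end_t)
}

#' Linear MAP extrapolation (LepMAP0)
#'
#' LepMAP0 continues an observed MAP change linearly: the prediction for
#' target time `t` uses the samples n and 2n seconds earlier,
#' `2 * MAP(t - n) - MAP(t - 2n)`. Predictions are emitted only where both
#' source samples exist in the same evaluation segment as the target.
#'
#' @param series A [vitals_series()].
#' @param n Extrapolation interval in seconds; positive multiple of 20.
#' @return Data frame: `target_t`, `value` (predicted MAP, mmHg), `n`.
#' @export
lepmap0_series <- function(series, n) {
  if (n <= 0 || n %% DT != 0)
    config_error("n must be a positive multiple of the 20-s sampling interval")
  g <- round(series$t / DT)
  i1 <- match(g - n / DT, g)
  i2 <- match(g - 2 * n / DT, g)
  ok <- !is.na(i1) & !is.na(i2) &
    series$segment == series$segment[ifelse(is.na(i2), 1L, i2)]
  data.frame(target_t = series$t[ok],
             value = 2 * series$map[i1[ok]] - series$map[i2[ok]],
             n = n)
}

#' Time-to-event extension for LepMAP0
#'
#' A plain LepMAP0 prediction fixes the warning time to its interval n. To
#' measure how much earlier the same extrapolation machinery would have
#' flagged the event, the two source samples are shifted back in steps of
#' x = 20 s and the line through them is extended forward to the onset of
#' hypotension, a horizon of h = n + x. The extension grows while every
#' extrapolated value stays below 65 mmHg, stopping at the first failure,
#' at missing history, or 20 min before onset; the result is therefore
#' always adjacent to the event.
#'
#' Requires the base prediction at the onset (x = 0) to be a correct
#' hypotension prediction (below 65 mmHg); otherwise the event was missed
#' and no extension exists.
#'
#' @param series A [vitals_series()].
#' @param event One event (a row of [detect_hypotension()] output, or any
#'   list with `onset_t`).
#' @param n Extrapolation interval in seconds; positive multiple of 20.
#' @param max_lookback Maximum horizon in seconds (default 1200 = 20 min).
#' @param threshold Prediction threshold (default 65 mmHg).
#' @return List with `tte` (extended time-to-event in seconds, `NA` if the
#'   base prediction missed or lacks history) and `reason` (`"ok"`,
#'   `"missed"` or `"no-history"`).
#' @export
lepmap0_tte_extension <- function(series, event, n, max_lookback = 1200,
                                  threshold = 65) {
  if (n <= 0 || n %% DT != 0)
    config_error("n must be a positive multiple of the 20-s sampling interval")
  onset <- event$onset_t
  g <- round(series$t / DT)
  g_on <- round(onset / DT)
  seg_on <- series$segment[match(g_on, g)]
  map_at <- function(time_s) {
    i <- match(round(time_s / DT), g)
    if (is.na(i) || series$segment[i] != seg_on) return(NA_real_)
    series$map[i]
  }
  m1 <- map_at(onset - n); m2 <- map_at(onset - 2 * n)
  if (is.na(m1) || is.na(m2)) return(list(tte = NA_real_, reason = "no-history"))
  if (2 * m1 - m2 >= threshold) return(list(tte = NA_real_, reason = "missed"))
  h <- n
  x <- DT
  while (n + x <= max_lookback) {
    hh <- n + x
    a <- map_at(onset - hh); b <- map_at(onset - hh - n)
    if (is.na(a) || is.na(b)) break
    pred <- a + (hh / n) * (a - b)
    if (pred >= threshold) break
    h <- hh
    x <- x + DT
  }
  list(tte = h, reason = "ok")
}
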