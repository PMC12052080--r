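# Classified items share one record layout for both schemes.
classified_items_frame <- function() {
  data.frame(kind = character(), label = character(),
             start_t = numeric(), end_t = numeric(),
             matched_event_onset = numeric(), tte = numeric())
}

check_episodes <- function(episodes) {
  if (nrow(episodes) < 2L) return(invisible(TRUE))
  ep <- episodes[order(episodes$start_t), , drop = FALSE]
  if (any(ep$start_t[-1L] < ep$end_t[-nrow(ep)] - EPS))
    integrity_error("alert episodes of one predictor overlap")
  invisible(TRUE)
}

# Episodes superseded by an intervention mark inside their active span
# (plus an optional post-episode grace window) are excluded from counting.
excluded_flags <- function(episodes, interventions, grace = 0) {
  if (nrow(episodes) == 0L) return(logical(0))
  if (is.null(interventions) || nrow(interventions) == 0L)
    return(rep(FALSE, nrow(episodes)))
  vapply(seq_len(nrow(episodes)), function(k) {
    any(interventions$t >= episodes$start_t[k] - EPS &
        interventions$t <= episodes$end_t[k] + grace + EPS)
  }, logical(1))
}

# Maximal non-alert periods: the record span minus episode spans and event
# spans, per evaluation segment.
non_alert_periods <- function(episodes, events, spans) {
  cut <- rbind(
    if (nrow(episodes) > 0L) data.frame(start = episodes$start_t, end = episodes$end_t),
    if (nrow(events) > 0L) data.frame(start = events$onset_t, end = events$end_t))
  interval_subtract(spans, cut)
}

#' Adjacency-oriented classification
#'
#' An alert episode is a true positive only if it activates before and
#' remains active until the onset of a hypotensive event: its coverage must
#' reach the sample immediately preceding the onset (`end_t >= onset`, with
#' episodes built under the event mask so they never extend into the event).
#' Episodes not adjacent to any event are false positives. Episodes
#' containing a blood-pressure-raising intervention mark are excluded from
#' either count. Each event is matched to at most one episode (the earliest
#' qualifying start); the time-to-event of a match is `onset - start_t`.
#'
#' Maximal non-alert periods (the record span minus episodes and events) are
#' false negatives when they directly precede an event onset, otherwise true
#' negatives.
#'
#' @param episodes Episodes from [threshold_episodes()] (one predictor),
#'   constructed with the hypotension mask.
#' @param events Events from [detect_hypotension()] on the same series.
#' @param interventions Marks from [detect_interventions()], or `NULL`.
#' @param spans Record spans from [record_spans()].
#' @param tol Adjacency tolerance in seconds (default 0: strictly adjacent).
#' @param grace Post-episode grace window for intervention exclusion
#'   (default 0 s).
#' @return A `classified_set`: list with `items` (one row per episode and
#'   per non-alert period: `kind`, `label` in TP/FP/TN/FN/EXCLUDED,
#'   `start_t`, `end_t`, `matched_event_onset`, `tte`), `event_match` (one
#'   row per event: `onset`, `matched_start`, `tte`), `scheme`, `window`.
#' @export
classify_adjacency <- function(episodes, events, interventions = NULL, spans,
                               tol = 0, grace = 0) {
  check_episodes(episodes)
  n_ep <- nrow(episodes)
  excl <- excluded_flags(episodes, interventions, grace)
  label <- rep("FP", n_ep)
  matched_onset <- rep(NA_real_, n_ep)
  tte <- rep(NA_real_, n_ep)
  ev_match <- data.frame(onset = events$onset_t,
                         matched_start = rep(NA_real_, nrow(events)),
                         tte = rep(NA_real_, nrow(events)))
  if (nrow(events) > 0L && n_ep > 0L) {
    taken <- rep(FALSE, n_ep)
    for (e in order(events$onset_t)) {
      onset <- events$onset_t[e]
      cand <- which(!excl & !taken &
                    episodes$start_t < onset - EPS &
                    episodes$end_t + tol >= onset - EPS)
      if (length(cand) == 0L) next
      k <- cand[which.min(episodes$start_t[cand])]
      taken[k] <- TRUE
      label[k] <- "TP"
      matched_onset[k] <- onset
      tte[k] <- onset - episodes$start_t[k]
      ev_match$matched_start[e] <- episodes$start_t[k]
      ev_match$tte[e] <- tte[k]
    }
  }
  label[excl] <- "EXCLUDED"
  ep_items <- data.frame(kind = rep("alert-episode", n_ep),
                         label = label,
                         start_t = episodes$start_t, end_t = episodes$end_t,
                         matched_event_onset = matched_onset, tte = tte)
  periods <- non_alert_periods(episodes, events, spans)
  per_label <- vapply(seq_len(nrow(periods)), function(k) {
    if (any(abs(events$onset_t - periods$end[k]) < EPS)) "FN" else "TN"
  }, character(1))
  per_items <- data.frame(kind = rep("non-alert-period", nrow(periods)),
                          label = per_label,
                          start_t = periods$start, end_t = periods$end,
                          matched_event_onset = NA_real_, tte = NA_real_)
  structure(list(items = rbind(ep_items, per_items),
                 event_match = ev_match,
                 scheme = "adjacency", window = NA_real_),
            class = "classified_set")
}

#' Timeframe-oriented classification
#'
#' An alert episode is a true positive if any hypotensive event begins
#' within the window (default 20 min) after the episode start; the alert may
#' fade away before the event. Episodes with no onset in their window are
#' false positives; intervention-superseded episodes are excluded. For
#' per-event accounting (missed events, time-to-event) each event's primary
#' match is the earliest-starting true-positive episode whose window
#' contains its onset.
#'
#' Non-alert periods followed by an event within the window are false
#' negatives only when no alert starts before that onset; when a later alert
#' intervenes before the event the period is discarded (not counted), and
#' periods with no event in the window are true negatives.
#'
#' @inheritParams classify_adjacency
#' @param window Timeframe length in seconds (default 1200 = 20 min); the
#'   window is half-open: an onset exactly at the episode start is not a
#'   prediction.
#' @return A `classified_set`; see [classify_adjacency()]. Labels may also
#'   include `DISCARDED`.
#' @export
classify_timeframe <- function(episodes, events, interventions = NULL, spans,
                               window = 1200, grace = 0) {
  if (window <= 0) config_error("window must be positive")
  check_episodes(episodes)
  n_ep <- nrow(episodes)
  excl <- excluded_flags(episodes, interventions, grace)
  label <- rep("FP", n_ep)
  matched_onset <- rep(NA_real_, n_ep)
  tte <- rep(NA_real_, n_ep)
  for (k in seq_len(n_ep)) {
    if (excl[k]) next
    hits <- events$onset_t[events$onset_t > episodes$start_t[k] + EPS &
                           events$onset_t <= episodes$start_t[k] + window + EPS]
    if (length(hits) > 0L) {
      label[k] <- "TP"
      matched_onset[k] <- min(hits)
      tte[k] <- min(hits) - episodes$start_t[k]
    }
  }
  label[excl] <- "EXCLUDED"
  ev_match <- data.frame(onset = events$onset_t,
                         matched_start = rep(NA_real_, nrow(events)),
                         tte = rep(NA_real_, nrow(events)))
  for (e in seq_len(nrow(events))) {
    onset <- events$onset_t[e]
    cand <- which(label == "TP" &
                  episodes$start_t < onset - EPS &
                  onset <= episodes$start_t + window + EPS)
    if (length(cand) == 0L) next
    k <- cand[which.min(episodes$start_t[cand])]
    ev_match$matched_start[e] <- episodes$start_t[k]
    ev_match$tte[e] <- onset - episodes$start_t[k]
  }
  ep_items <- data.frame(kind = rep("alert-episode", n_ep),
                         label = label,
                         start_t = episodes$start_t, end_t = episodes$end_t,
                         matched_event_onset = matched_onset, tte = tte)
  periods <- non_alert_periods(episodes, events, spans)
  per_label <- vapply(seq_len(nrow(periods)), function(k) {
    hits <- events$onset_t[events$onset_t > periods$start[k] + EPS &
                           events$onset_t <= periods$start[k] + window + EPS]
    if (length(hits) == 0L) return("TN")
    onset <- min(hits)
    later_alert <- n_ep > 0L &&
      any(episodes$start_t > periods$start[k] + EPS &
          episodes$start_t < onset - EPS)
    if (later_alert) "DISCARDED" else "FN"
  }, character(1))
  per_items <- data.frame(kind = rep("non-alert-period", nrow(periods)),
                          label = per_label,
                          start_t = periods$start, end_t = periods$end,
                          matched_event_onset = NA_real_, tte = NA_real_)
  structure(list(items = rbind(ep_items, per_items),
                 event_match = ev_match,
                 scheme = "timeframe", window = window),
            class = "classified_set")
}

#' @export
print.classified_set <- function(x, ...) {
  tab <- table(factor(x$items$label,
                      levels = c("TP", "FP", "TN", "FN", "EXCLUDED", "DISCARDED")))
  cat(sprintf("<classified_set> scheme=%s%s: %s\n", x$scheme,
              if (!is.na(x$window)) sprintf(" (window %gs)", x$window) else "",
              paste(names(tab), tab, sep = "=", collapse = " ")))
  invisible(x)
}
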