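#' Bootstrap configuration
#'
#' Confidence intervals are obtained by resampling patients with replacement
#' (the resampling unit respects within-patient correlation of alerts and
#' events), recomputing each metric on every resample, and taking the
#' 2.5/97.5 percentiles; the reported centre is the bootstrap mean.
#'
#' @param iterations Number of bootstrap resamples (default 2000).
#' @param seed Integer seed; the bootstrap is bit-reproducible given the seed.
#' @return Object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(iterations = 2000, seed = 1L) {
  if (iterations < 1) config_error("iterations must be >= 1")
  structure(list(iterations = as.integer(iterations), seed = as.integer(seed),
                 unit = "patient"),
            class = "bootstrap_config")
}

# Per-patient sufficient statistics for all summary metrics.
patient_stats <- function(cs, events) {
  it <- cs$items
  cnt <- function(lbl) sum(it$label == lbl)
  matched <- !is.na(cs$event_match$tte)
  list(tp = cnt("TP"), fp = cnt("FP"), tn = cnt("TN"), fn = cnt("FN"),
       excluded = cnt("EXCLUDED"), discarded = cnt("DISCARDED"),
       n_events = nrow(cs$event_match),
       n_matched = sum(matched),
       tte_sum = sum(cs$event_match$tte[matched]),
       tte = cs$event_match$tte)
}

# Per-patient sufficient statistics as a matrix (one row per patient).
stats_matrix <- function(st_list) {
  fields <- c("tp", "fp", "tn", "fn", "n_events", "n_matched", "tte_sum")
  m <- vapply(st_list, function(s) unlist(s[fields]), numeric(length(fields)))
  m <- t(m)
  colnames(m) <- fields
  m
}

metric_from_matrix <- function(S, idx) {
  tp <- sum(S[idx, "tp"]); fp <- sum(S[idx, "fp"])
  tn <- sum(S[idx, "tn"]); fn <- sum(S[idx, "fn"])
  nev <- S[idx, "n_events"]; nma <- S[idx, "n_matched"]
  tsum <- sum(S[idx, "tte_sum"])
  has_ev <- nev > 0
  prop_missed <- 100 * (nev[has_ev] - nma[has_ev]) / nev[has_ev]
  c(ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_,
    tte_min = if (sum(nma) > 0) tsum / sum(nma) / 60 else NA_real_,
    missed_median = if (length(prop_missed) > 0) stats::median(prop_missed) else NA_real_,
    missed_mean = if (length(prop_missed) > 0) mean(prop_missed) else NA_real_)
}

#' Summarise a predictor's classified cohort
#'
#' Computes the three headline metrics -- mean time-to-event over correctly
#' predicted events (minutes), positive and negative predictive value from
#' pooled counts (%), and the missed-event rate (per-patient proportion of
#' events without a matched alert, %; both the median and the mean of the
#' per-patient proportions are reported, patients without events excluded)
#' -- with percentile bootstrap confidence intervals over patients.
#'
#' @param classified Named list (one `classified_set` per patient) for a
#'   single predictor and scheme.
#' @param events Named list of event tables per patient (same names).
#' @param boot A [bootstrap_config()].
#' @return List with `point` (pooled point estimates), `boot_mean`, `ci_lo`,
#'   `ci_hi` (named vectors over ppv/npv/tte_min/missed_median/missed_mean)
#'   and `counts` (pooled TP/FP/TN/FN/EXCLUDED/DISCARDED, events, matched,
#'   patients).
#' @export
summarize_predictor <- function(classified, events, boot = bootstrap_config()) {
  stopifnot(length(classified) == length(events))
  st <- lapply(seq_along(classified), function(i)
    patient_stats(classified[[i]], events[[i]]))
  n <- length(st)
  S <- stats_matrix(st)
  point <- metric_from_matrix(S, seq_len(n))
  counts <- c(tp = sum(S[, "tp"]), fp = sum(S[, "fp"]),
              tn = sum(S[, "tn"]), fn = sum(S[, "fn"]),
              excluded = sum(vapply(st, `[[`, numeric(1), "excluded")),
              discarded = sum(vapply(st, `[[`, numeric(1), "discarded")),
              events = sum(S[, "n_events"]), matched = sum(S[, "n_matched"]),
              patients = n)
  B <- boot$iterations
  dist <- with_seed(boot$seed, {
    idx_mat <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    t(apply(idx_mat, 1L, function(idx) metric_from_matrix(S, idx)))
  })
  list(point = point,
       boot_mean = colMeans(dist, na.rm = TRUE),
       ci_lo = apply(dist, 2L, stats::quantile, probs = 0.025, na.rm = TRUE, names = FALSE),
       ci_hi = apply(dist, 2L, stats::quantile, probs = 0.975, na.rm = TRUE, names = FALSE),
       counts = counts)
}

#' Paired time gain between two predictors
#'
#' For every hypotensive event, the gain of predictor A over predictor B is
#' `tte_A - tte_B` in minutes, where an event missed by a predictor
#' contributes a time-to-event of 0 (so if A alerts 2 min ahead and B misses
#' the event, the gain is 2 min). The mean gain carries a patient-level
#' bootstrap confidence interval.
#'
#' @param classified_a,classified_b Named per-patient lists of
#'   `classified_set`s for the two predictors, over identical events.
#' @param boot A [bootstrap_config()].
#' @return List with `mean_gain_min`, `boot_mean`, `ci_lo`, `ci_hi`,
#'   `n_events`, and `gains` (per-event gains in minutes).
#' @export
paired_time_gain <- function(classified_a, classified_b,
                             boot = bootstrap_config()) {
  stopifnot(length(classified_a) == length(classified_b))
  per_patient <- lapply(seq_along(classified_a), function(i) {
    ma <- classified_a[[i]]$event_match
    mb <- classified_b[[i]]$event_match
    if (nrow(ma) != nrow(mb) || (nrow(ma) > 0L && any(abs(ma$onset - mb$onset) > EPS)))
      integrity_error("paired comparison requires identical event lists")
    ga <- ifelse(is.na(ma$tte), 0, ma$tte)
    gb <- ifelse(is.na(mb$tte), 0, mb$tte)
    (ga - gb) / 60
  })
  gains <- unlist(per_patient)
  n <- length(per_patient)
  sums <- vapply(per_patient, sum, numeric(1))
  cnts <- vapply(per_patient, length, numeric(1))
  B <- boot$iterations
  dist <- with_seed(boot$seed, {
    idx_mat <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    apply(idx_mat, 1L, function(idx) {
      tot <- sum(cnts[idx])
      if (tot == 0) NA_real_ else sum(sums[idx]) / tot
    })
  })
  list(mean_gain_min = if (length(gains) > 0) mean(gains) else NA_real_,
       boot_mean = mean(dist, na.rm = TRUE),
       ci_lo = unname(stats::quantile(dist, 0.025, na.rm = TRUE)),
       ci_hi = unname(stats::quantile(dist, 0.975, na.rm = TRUE)),
       n_events = length(gains),
       gains = gains)
}

# Pooled (map, hpi) samples after masking events and intervention outliers.
pooled_index_pairs <- function(cohort, events_by_patient = NULL,
                               interventions_by_patient = NULL,
                               outlier_window = 120) {
  pieces <- lapply(names(cohort), function(id) {
    s <- cohort[[id]]
    if (!has_hpi(s)) capability_error("index signal absent from the cohort")
    keep <- rep(TRUE, n_samples(s))
    ev <- events_by_patient[[id]]
    if (!is.null(ev) && nrow(ev) > 0L) {
      for (k in seq_len(nrow(ev)))
        keep[s$t >= ev$onset_t[k] - EPS & s$t < ev$end_t[k] - EPS] <- FALSE
    }
    iv <- interventions_by_patient[[id]]
    if (!is.null(iv) && nrow(iv) > 0L) {
      for (k in seq_len(nrow(iv)))
        keep[abs(s$t - iv$t[k]) <= outlier_window + EPS] <- FALSE
    }
    data.frame(map = s$map[keep], hpi = s$hpi[keep])
  })
  do.call(rbind, pieces)
}

#' MAP distribution per index value
#'
#' For each integer index value 0-100, summarises the concurrent MAP values
#' pooled over the cohort, excluding samples inside hypotensive events and
#' samples within an outlier window around detected intervention marks
#' (default +/- 120 s, the length of the long intervention-detection
#' window). A wide MAP spread at a fixed index value argues against the
#' index simply mirroring MAP.
#'
#' @param cohort A [cohort()] whose series carry the index signal.
#' @param events_by_patient,interventions_by_patient Optional named lists of
#'   per-patient event tables / intervention marks used for masking.
#' @param outlier_window Half-width of the intervention exclusion window (s).
#' @return Data frame per observed integer index value: `hpi`, `n`,
#'   `map_median`, `map_q1`, `map_q3`, `map_min`, `map_max`.
#' @export
hpi_map_distribution <- function(cohort, events_by_patient = NULL,
                                 interventions_by_patient = NULL,
                                 outlier_window = 120) {
  pairs <- pooled_index_pairs(cohort, events_by_patient,
                              interventions_by_patient, outlier_window)
  empty <- data.frame(hpi = integer(), n = integer(), map_median = numeric(),
                      map_q1 = numeric(), map_q3 = numeric(),
                      map_min = numeric(), map_max = numeric())
  if (nrow(pairs) == 0L) return(empty)
  pairs$hpi_int <- as.integer(round(pairs$hpi))
  out <- do.call(rbind, lapply(split(pairs, pairs$hpi_int), function(d) {
    data.frame(hpi = d$hpi_int[1L], n = nrow(d),
               map_median = stats::median(d$map),
               map_q1 = q25(d$map), map_q3 = q75(d$map),
               map_min = min(d$map), map_max = max(d$map))
  }))
  rownames(out) <- NULL
  out[order(out$hpi), , drop = FALSE]
}

#' Spearman rank correlation between the index and MAP
#'
#' Pools concurrent (index, MAP) pairs over the cohort -- optionally masking
#' hypotensive events and intervention outliers, to probe whether sudden
#' treatment-induced MAP rises inflate the correlation -- and computes
#' Spearman's rho with mid-ranked ties.
#'
#' @inheritParams hpi_map_distribution
#' @return Spearman's rho, or `NA` when fewer than 3 pairs remain.
#' @export
spearman_hpi_map <- function(cohort, events_by_patient = NULL,
                             interventions_by_patient = NULL,
                             outlier_window = 120) {
  pairs <- pooled_index_pairs(cohort, events_by_patient,
                              interventions_by_patient, outlier_window)
  if (nrow(pairs) < 3L) return(NA_real_)
  stats::cor(pairs$hpi, pairs$map, method = "spearman")
}
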