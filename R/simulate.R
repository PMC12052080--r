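#' Simulation configuration
#'
#' Defaults are calibrated so a default cohort reproduces the statistical
#' structure of an intraoperative non-cardiac-surgery cohort: procedure
#' durations log-normal with a median around 3.6 h; a median of about 3
#' hypotensive events per patient with a wide right tail; hypotension
#' (MAP < 65 mmHg) occupying roughly 12% of monitored time; occasional
#' abrupt intervention-like MAP jumps from a low baseline; and a 0-100
#' index signal that rises ahead of MAP declines.
#'
#' The MAP path is a per-patient baseline plus a slow mean-reverting
#' (Ornstein-Uhlenbeck) drift, with smooth negative excursions superimposed
#' for hypotensive events (a ramp down to the threshold, a sub-threshold
#' lobe, a recovery ramp) and for sub-threshold "near-miss" dips that never
#' cross 65 mmHg; white measurement noise is added on top. The index is a
#' logistic function of the current MAP level and the short-horizon MAP
#' slope, scaled to 0-100, with additive noise -- anticipatory behaviour
#' without claiming to reproduce any proprietary algorithm.
#'
#' @param n_patients Number of patients (default 91).
#' @param seed Master seed; per-patient seeds are derived from it so cohorts
#'   are reproducible patient-by-patient.
#' @param ... Overrides for any default parameter (see the source for the
#'   full list: duration distribution, baseline/drift/noise levels, event
#'   count and geometry, near-miss and intervention rates, index link
#'   coefficients).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_patients = 91, seed = 1L, ...) {
  cfg <- list(
    n_patients = n_patients, seed = as.integer(seed),
    # procedure duration (s): log-normal, median 3.6 h, floor 30 min
    duration_meanlog = log(3.6 * 3600), duration_sdlog = 0.39,
    duration_min_s = 1800,
    # baseline level, slow drift, measurement noise
    map_baseline_mean = 80, map_baseline_sd = 4,
    ou_theta = 1 / 600, ou_sd = 3, noise_sd = 1.0,
    # hypotensive events: count, sub-65 lobe width, depth below 65
    event_count_size = 1.4, event_count_mu = 6,
    event_width_meanlog = log(400), event_width_sdlog = 0.6,
    event_width_min = 60, event_width_max = 1200,
    event_depth_min = 5, event_depth_max = 12,
    ramp_min = 120, ramp_max = 360,
    plateau_min = 5L, plateau_max = 9L, plateau_level = 67.5,
    # spontaneous recovery: slow climb while MAP is low, so natural
    # normalisation never looks like a treatment to the rise detector
    recovery_rate = 0.8, recovery_free_above = 72,
    # sub-threshold near-miss dips (never below 65)
    nearmiss_rate = 5, nearmiss_nadir_min = 67, nearmiss_nadir_max = 75,
    # intervention-like MAP jumps during low-MAP episodes
    intervention_prob = 0.35, intervention_jump_min = 6,
    intervention_jump_max = 15,
    # index link: 100 * plogis(b0 + b1*(anchor - MAP) + b2*(-slope/min))
    hpi_b0 = -3.2, hpi_b1 = 0.9, hpi_b2 = 0.9,
    hpi_anchor = 75, hpi_slope_window_s = 120, hpi_noise_sd = 3,
    hypo_threshold = 65)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown) > 0L)
    config_error(paste0("unknown sim_config parameter(s): ",
                        paste(unknown, collapse = ", ")))
  cfg[names(override)] <- override
  structure(cfg, class = "sim_config")
}

# Raised-cosine interpolation from a to b over k samples (excludes a itself).
ease <- function(a, b, k) {
  if (k <= 0L) return(numeric(0))
  w <- (1 - cos(pi * seq_len(k) / k)) / 2
  a + (b - a) * w
}

#' Simulate one patient
#'
#' Generates a 20-s-sampled MAP series with the configured drift, event and
#' near-miss excursions and intervention jumps, plus the index column, and
#' returns the ground truth alongside: the true event intervals are obtained
#' by applying the hypotensive-event definition to the noise-free MAP path,
#' so they satisfy the event rules by construction, and noise is small
#' relative to the excursion depth so the detector recovers them from the
#' noisy trace.
#'
#' @param config A [sim_config()].
#' @param patient_seed Integer seed for this patient.
#' @param patient_id Identifier for the series.
#' @return List with `series` (a [vitals_series()]) and `truth` (list with
#'   `events`, the event table of the noise-free path, and `interventions`,
#'   the times of injected jumps).
#' @export
simulate_patient <- function(config, patient_seed, patient_id = "sim") {
  with_seed(patient_seed, simulate_patient_impl(config, patient_id))
}

simulate_patient_impl <- function(cfg, patient_id) {
  dur <- max(cfg$duration_min_s,
             stats::rlnorm(1, cfg$duration_meanlog, cfg$duration_sdlog))
  n <- max(90L, as.integer(round(dur / DT)))
  t <- (seq_len(n) - 1L) * DT

  # slow mean-reverting drift around the patient's baseline
  base <- stats::rnorm(1, cfg$map_baseline_mean, cfg$map_baseline_sd)
  base <- min(max(base, 75), 95)
  a <- exp(-cfg$ou_theta * DT)
  innov_sd <- cfg$ou_sd * sqrt(1 - a^2)
  x <- numeric(n)
  x[1L] <- stats::rnorm(1, 0, cfg$ou_sd)
  for (i in 2:n) x[i] <- a * x[i - 1L] + stats::rnorm(1, 0, innov_sd)
  m <- base + x  # noise-free path; excursions are carved in below

  thr <- cfg$hypo_threshold
  n_ev <- stats::rnbinom(1, size = cfg$event_count_size, mu = cfg$event_count_mu)
  n_nm <- stats::rpois(1, cfg$nearmiss_rate)
  kinds <- c(rep("event", n_ev), rep("near", n_nm))
  if (length(kinds) > 0L) kinds <- sample(kinds)
  placed <- data.frame(start = numeric(), end = numeric())
  iv_times <- numeric()

  # climb slowly (< 5 mmHg / 20 s and < 8 mmHg / 2 min) while MAP is below
  # the detector-exempt level, then ease back to the local baseline
  recovery_tail <- function(v0, b1) {
    free <- cfg$recovery_free_above
    climb <- if (v0 + cfg$recovery_rate < free)
      seq(v0 + cfg$recovery_rate, free, by = cfg$recovery_rate)
    else numeric(0)
    c(climb, ease(free, max(b1, free + 1), 10L))
  }

  for (kind in kinds) {
    treat <- FALSE
    if (kind == "event") {
      k_ramp <- max(4L, as.integer(round(stats::runif(1, cfg$ramp_min, cfg$ramp_max) / DT)))
      p <- sample(cfg$plateau_min:cfg$plateau_max, 1L)
      lobe_s <- min(max(stats::rlnorm(1, cfg$event_width_meanlog, cfg$event_width_sdlog),
                        cfg$event_width_min), cfg$event_width_max)
      k_lobe <- max(3L, as.integer(round(lobe_s / DT)))
      depth <- stats::runif(1, cfg$event_depth_min, cfg$event_depth_max)
      treat <- stats::runif(1) < cfg$intervention_prob && k_lobe >= 5L
      cut <- if (treat) sample(3:(k_lobe - 1L), 1L) else k_lobe
      jump <- stats::runif(1, cfg$intervention_jump_min, cfg$intervention_jump_max)
    } else {
      k_dn <- sample(4:12, 1L)
      dwell <- sample(1:3, 1L)
      nadir <- stats::runif(1, cfg$nearmiss_nadir_min, cfg$nearmiss_nadir_max)
      treat <- nadir < 70 && stats::runif(1) < 0.3 * cfg$intervention_prob
      jump <- stats::runif(1, cfg$intervention_jump_min, cfg$intervention_jump_max)
    }
    # conservative footprint bound for placement (recovery length depends on
    # the local baseline, bounded by the deepest possible climb + ease tail)
    k_rec_max <- length(seq(thr - cfg$event_depth_max, cfg$recovery_free_above,
                            by = cfg$recovery_rate)) + 10L
    k_bound <- if (kind == "event") k_ramp + 1L + p + k_lobe + k_rec_max
               else k_dn + dwell + k_rec_max
    if (k_bound + 4L >= n) next
    ok <- FALSE
    for (try in 1:30) {  # place without overlap, keep >= 120 s apart
      i0 <- sample.int(n - k_bound - 2L, 1L) + 1L
      cand <- c(t[i0], t[i0] + k_bound * DT)
      if (nrow(placed) == 0L ||
          all(cand[2L] + 120 < placed$start | cand[1L] - 120 > placed$end)) {
        ok <- TRUE; break
      }
    }
    if (!ok) next
    b0 <- m[i0]; b1 <- m[i0 + k_bound - 1L]
    if (kind == "event") {
      # descent to just above 70, one transition sample, then a shallow
      # sub-70 plateau whose last samples sit ~2 mmHg above the threshold
      wobble <- 0.3 * sin(pi * seq_len(p) / (p + 1L))
      head_prof <- c(ease(b0, 70.5, k_ramp), 69,
                     rep(cfg$plateau_level, p) - wobble)
      wob <- 0.2 * depth * sin(pi * seq_len(k_lobe) / (k_lobe + 1L))
      lobe <- (rep(thr - depth, k_lobe) - wob)[seq_len(cut)]
      if (treat) {
        post_v <- max(lobe[cut] + jump, 66.5)
        prof <- c(head_prof, lobe, post_v, recovery_tail(post_v, b1))
        iv_offset <- length(head_prof) + cut + 1L
      } else {
        prof <- c(head_prof, lobe, recovery_tail(lobe[cut], b1))
        iv_offset <- NA_integer_
      }
    } else {
      head_prof <- c(ease(b0, nadir, k_dn), rep(nadir, dwell))
      if (treat) {
        post_v <- nadir + jump
        prof <- c(head_prof, post_v, recovery_tail(post_v, b1))
        iv_offset <- length(head_prof) + 1L
      } else {
        prof <- c(head_prof, recovery_tail(nadir, b1))
        iv_offset <- NA_integer_
      }
    }
    k_tot <- length(prof)
    if (i0 + k_tot - 1L > n) next
    m[i0:(i0 + k_tot - 1L)] <- prof
    placed <- rbind(placed, data.frame(start = t[i0], end = t[i0] + k_tot * DT))
    if (!is.na(iv_offset))
      iv_times <- c(iv_times, t[i0] + (iv_offset - 1L) * DT)
  }
  m <- pmin(pmax(m, 35), 130)

  truth_series <- new_vitals_series(patient_id, t, m)
  truth_events <- detect_hypotension(truth_series, threshold = thr)

  map <- pmax(m + stats::rnorm(n, 0, cfg$noise_sd), 30)
  # index: logistic in level and 2-min decline rate (mmHg/min), on noisy MAP
  kw <- max(1L, round(cfg$hpi_slope_window_s / DT))
  slope <- c(rep(0, kw), (map[(kw + 1L):n] - map[1:(n - kw)]) / (kw * DT / 60))
  lin <- cfg$hpi_b0 + cfg$hpi_b1 * (cfg$hpi_anchor - map) + cfg$hpi_b2 * (-slope)
  hpi <- round(pmin(pmax(100 * stats::plogis(lin) +
                           stats::rnorm(n, 0, cfg$hpi_noise_sd), 0), 100))
  list(series = vitals_series(patient_id, t, map, hpi = hpi),
       truth = list(events = truth_events,
                    interventions = sort(iv_times)))
}

#' Simulate a cohort
#'
#' Per-patient seeds are derived deterministically from the master seed, so
#' the cohort is reproducible patient-by-patient. The calibration summary
#' reports the cohort-level statistics the defaults are tuned to: median
#' detected events per patient, fraction of monitored time spent
#' hypotensive, and the median per-patient cumulative hypotensive time.
#'
#' @param config A [sim_config()].
#' @return List with `cohort` (a [cohort()]), `truth` (named per-patient
#'   list), and `calibration` (list with `median_events_per_patient`,
#'   `hypo_time_fraction`, `median_hypo_min`, `n_events_total`,
#'   `monitored_min_total`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  n <- config$n_patients
  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max - 1L, n))
  ids <- sprintf("P%03d", seq_len(n))
  sims <- lapply(seq_len(n), function(i)
    simulate_patient(config, seeds[i], ids[i]))
  co <- cohort(lapply(sims, `[[`, "series"))
  truth <- lapply(sims, `[[`, "truth")
  names(truth) <- ids
  ev <- lapply(co, detect_hypotension, threshold = config$hypo_threshold)
  n_events <- vapply(ev, nrow, integer(1))
  hypo_min <- vapply(ev, function(e) sum(e$sub_time_s) / 60, numeric(1))
  mon_min <- vapply(co, monitored_minutes, numeric(1))
  list(cohort = co, truth = truth,
       calibration = list(
         median_events_per_patient = stats::median(n_events),
         hypo_time_fraction = sum(hypo_min) / sum(mon_min),
         median_hypo_min = stats::median(hypo_min),
         n_events_total = sum(n_events),
         monitored_min_total = sum(mon_min)))
}
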