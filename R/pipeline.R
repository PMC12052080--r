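#' Run the full evaluation pipeline over a cohort
#'
#' For every patient: detect hypotensive events and intervention artefacts,
#' build the event mask, construct alert episodes for every predictor in the
#' battery, and classify them under the requested scheme(s). Then summarise
#' each predictor with bootstrap confidence intervals, compute paired time
#' gains against the reference predictors (adjacency scheme, over all
#' events), and -- when the index signal is present -- the per-index MAP
#' distribution and the index-MAP Spearman correlation.
#'
#' @param cohort A [cohort()], or a path to a vitals CSV.
#' @param battery Named list of [alert_definition()]s (default
#'   [default_battery()]). Predictors requiring an absent index signal raise
#'   a capability error naming the offending predictor.
#' @param schemes Character subset of `c("adjacency", "timeframe")`.
#' @param window Timeframe window in seconds (default 1200).
#' @param boot A [bootstrap_config()].
#' @param reference Predictor ids used as baselines for the paired time-gain
#'   columns (defaults: the popup and instant index alerts).
#' @param out_dir Optional directory; when given, writes the classified
#'   items, the metrics table, the paired gains, the per-index MAP table and
#'   a run manifest as CSV/JSON.
#' @return List of class `evaluation_bundle`: `metrics` (data frame, one row
#'   per predictor x scheme), `gains` (data frame of paired comparisons),
#'   `classified` (nested list scheme -> predictor -> patient),
#'   `events`, `interventions` (per patient), `hpi_table`, `spearman_rho`,
#'   `calibration_counts`, `manifest`.
#' @export
run_evaluation <- function(cohort, battery = default_battery(),
                           schemes = c("adjacency"), window = 1200,
                           boot = bootstrap_config(),
                           reference = c("HPI-85-popup", "HPI-85"),
                           out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_vitals_csv(cohort)
  if (length(battery) == 0L) config_error("the predictor battery is empty")
  schemes <- match.arg(schemes, c("adjacency", "timeframe"), several.ok = TRUE)
  if (length(schemes) == 0L) config_error("at least one scheme is required")
  ids <- names(cohort)

  events <- lapply(cohort, detect_hypotension)
  interventions <- lapply(cohort, detect_interventions)
  spans <- lapply(cohort, record_spans)
  masks <- lapply(events, event_mask)

  any_hpi_defn <- any(vapply(battery, function(d) d$signal == "HPI", logical(1)))
  if (any_hpi_defn) {
    lacking <- ids[!vapply(cohort, has_hpi, logical(1))]
    if (length(lacking) > 0L) {
      offenders <- names(battery)[vapply(battery, function(d) d$signal == "HPI",
                                         logical(1))]
      capability_error(paste0(
        "predictor(s) ", paste(offenders, collapse = ", "),
        " require an index signal absent for patient(s) ",
        paste(utils::head(lacking, 5L), collapse = ", ")))
    }
  }

  classified <- list()
  for (scheme in schemes) classified[[scheme]] <- list()
  episodes_by_pred <- list()
  for (pid in names(battery)) {
    defn <- battery[[pid]]
    eps <- lapply(ids, function(id)
      threshold_episodes(cohort[[id]], defn, mask = masks[[id]]))
    names(eps) <- ids
    episodes_by_pred[[pid]] <- eps
    for (scheme in schemes) {
      classified[[scheme]][[pid]] <- lapply(ids, function(id) {
        if (scheme == "adjacency")
          classify_adjacency(eps[[id]], events[[id]], interventions[[id]],
                             spans[[id]])
        else
          classify_timeframe(eps[[id]], events[[id]], interventions[[id]],
                             spans[[id]], window = window)
      })
      names(classified[[scheme]][[pid]]) <- ids
    }
  }

  metrics <- do.call(rbind, lapply(names(battery), function(pid) {
    do.call(rbind, lapply(schemes, function(scheme) {
      s <- summarize_predictor(classified[[scheme]][[pid]], events, boot)
      data.frame(predictor_id = pid, scheme = scheme,
                 tte_min = s$boot_mean[["tte_min"]],
                 tte_lo = s$ci_lo[["tte_min"]], tte_hi = s$ci_hi[["tte_min"]],
                 ppv = s$boot_mean[["ppv"]],
                 ppv_lo = s$ci_lo[["ppv"]], ppv_hi = s$ci_hi[["ppv"]],
                 npv = s$boot_mean[["npv"]],
                 npv_lo = s$ci_lo[["npv"]], npv_hi = s$ci_hi[["npv"]],
                 missed_pct = s$boot_mean[["missed_median"]],
                 missed_lo = s$ci_lo[["missed_median"]],
                 missed_hi = s$ci_hi[["missed_median"]],
                 missed_mean_pct = s$boot_mean[["missed_mean"]],
                 ppv_point = s$point[["ppv"]], tte_point_min = s$point[["tte_min"]],
                 tp = s$counts[["tp"]], fp = s$counts[["fp"]],
                 tn = s$counts[["tn"]], fn = s$counts[["fn"]],
                 excluded = s$counts[["excluded"]],
                 discarded = s$counts[["discarded"]],
                 events = s$counts[["events"]], matched = s$counts[["matched"]])
    }))
  }))
  rownames(metrics) <- NULL

  gains <- NULL
  ref_present <- intersect(reference, names(battery))
  gain_scheme <- if ("adjacency" %in% schemes) "adjacency" else schemes[1L]
  if (length(ref_present) > 0L) {
    gains <- do.call(rbind, lapply(ref_present, function(ref) {
      others <- setdiff(names(battery), ref)
      do.call(rbind, lapply(others, function(pid) {
        g <- paired_time_gain(classified[[gain_scheme]][[ref]],
                              classified[[gain_scheme]][[pid]], boot)
        data.frame(reference = ref, predictor_id = pid, scheme = gain_scheme,
                   mean_gain_min = g$boot_mean, gain_lo = g$ci_lo,
                   gain_hi = g$ci_hi, n_events = g$n_events)
      }))
    }))
    rownames(gains) <- NULL
  }

  all_hpi <- all(vapply(cohort, has_hpi, logical(1)))
  hpi_table <- if (all_hpi)
    hpi_map_distribution(cohort, events, interventions) else NULL
  rho <- if (all_hpi) spearman_hpi_map(cohort, events, interventions) else NA_real_

  counts <- list(
    patients = length(cohort),
    events_total = sum(vapply(events, nrow, integer(1))),
    interventions_total = sum(vapply(interventions, nrow, integer(1))),
    monitored_min_total = sum(vapply(cohort, monitored_minutes, numeric(1))))

  bundle <- structure(list(
    metrics = metrics, gains = gains, classified = classified,
    episodes = episodes_by_pred, events = events,
    interventions = interventions,
    hpi_table = hpi_table, spearman_rho = rho,
    calibration_counts = counts,
    manifest = list(
      package_version = as.character(utils::packageVersion("hypoalert")),
      boot_iterations = boot$iterations, boot_seed = boot$seed,
      schemes = schemes, window = window,
      battery = lapply(battery, unclass), reference = reference)),
    class = "evaluation_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$gains))
    utils::write.csv(bundle$gains, file.path(out_dir, "paired_gains.csv"),
                     row.names = FALSE)
  if (!is.null(bundle$hpi_table))
    utils::write.csv(bundle$hpi_table, file.path(out_dir, "hpi_map_table.csv"),
                     row.names = FALSE)
  items <- do.call(rbind, lapply(names(bundle$classified), function(scheme) {
    do.call(rbind, lapply(names(bundle$classified[[scheme]]), function(pid) {
      do.call(rbind, lapply(names(bundle$classified[[scheme]][[pid]]), function(id) {
        it <- bundle$classified[[scheme]][[pid]][[id]]$items
        if (nrow(it) == 0L) return(NULL)
        cbind(data.frame(patient_id = id, predictor_id = pid, scheme = scheme),
              it)
      }))
    }))
  }))
  utils::write.csv(items, file.path(out_dir, "classified_items.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    c(bundle$manifest,
      list(spearman_rho = bundle$spearman_rho,
           counts = bundle$calibration_counts)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Figures for an evaluation bundle
#'
#' Writes (a) a per-predictor panel of the percentage of hypotensive events
#' preceded by an alert together with the positive predictive value, and (b)
#' when the index table is available, the spread of MAP values observed at
#' each index value (median, interquartile ribbon, min-max range).
#'
#' @param bundle An `evaluation_bundle` from [run_evaluation()].
#' @param out_dir Output directory for the PNG files.
#' @param scheme Which scheme's metrics to plot (default the first present).
#' @return Character vector of files written, invisibly.
#' @export
make_figures <- function(bundle, out_dir, scheme = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  m <- bundle$metrics
  if (is.null(scheme)) scheme <- m$scheme[1L]
  m <- m[m$scheme == scheme, , drop = FALSE]
  m$pct_preceded <- 100 * m$matched / pmax(m$events, 1)
  m$predictor_id <- factor(m$predictor_id, levels = m$predictor_id)
  long <- rbind(
    data.frame(predictor_id = m$predictor_id, metric = "% events preceded by an alert",
               value = m$pct_preceded),
    data.frame(predictor_id = m$predictor_id, metric = "PPV (%)", value = m$ppv))
  p1 <- ggplot2::ggplot(long,
          ggplot2::aes(x = predictor_id, y = value,
                       fill = metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "%", fill = NULL,
                  title = sprintf("Alert performance (%s-oriented)", scheme)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  f1 <- file.path(out_dir, "alert_performance.png")
  ggplot2::ggsave(f1, p1, width = 9, height = 4.5, dpi = 150)
  files <- f1
  if (!is.null(bundle$hpi_table)) {
    h <- bundle$hpi_table
    p2 <- ggplot2::ggplot(h, ggplot2::aes(x = hpi)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = map_min, ymax = map_max),
                           fill = "grey85") +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = map_q1, ymax = map_q3),
                           fill = "grey60") +
      ggplot2::geom_line(ggplot2::aes(y = map_median)) +
      ggplot2::labs(x = "index value", y = "MAP (mmHg)",
                    title = "MAP distribution per index value") +
      ggplot2::theme_minimal()
    f2 <- file.path(out_dir, "hpi_map_spread.png")
    ggplot2::ggsave(f2, p2, width = 7, height = 4.5, dpi = 150)
    files <- c(files, f2)
  } else {
    warning("index table missing; skipping the MAP-spread panel")
  }
  invisible(files)
}

#' @export
print.evaluation_bundle <- function(x, ...) {
  cat(sprintf("<evaluation_bundle> %d patients, %d events, %d predictors, scheme(s): %s\n",
              x$calibration_counts$patients, x$calibration_counts$events_total,
              length(unique(x$metrics$predictor_id)),
              paste(unique(x$metrics$scheme), collapse = ", ")))
  invisible(x)
}
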