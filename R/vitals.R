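#' Per-patient haemodynamic time series
#'
#' A `vitals_series` holds one patient's timestamped mean arterial pressure
#' (MAP, mmHg) samples at a nominal 20-s interval (0.05 Hz), optionally with
#' a concurrent 0-100 hypotension-index column. Each sample is timestamped at
#' the start of the 20-s interval it represents, so a sample at time `t`
#' covers `[t, t + 20)`.
#'
#' Sampling gaps larger than 20 s are recorded as explicit gap intervals;
#' gaps longer than 60 s split the series into independent evaluation
#' segments, across which no event or alert episode may extend.
#'
#' @param patient_id Opaque patient identifier (coerced to character).
#' @param t Sample times in seconds, strictly increasing.
#' @param map MAP in mmHg per sample; finite and positive.
#' @param hpi Optional index value in `[0, 100]` per sample, or `NULL`.
#' @return An object of class `vitals_series` with elements `patient_id`,
#'   `t`, `map`, `hpi` (or `NULL`), `gaps` (data frame of gap intervals),
#'   and `segment` (integer segment id per sample).
#' @export
vitals_series <- function(patient_id, t, map, hpi = NULL) {
  s <- new_vitals_series(patient_id, t, map, hpi)
  rep_ <- validate_series(s)
  if (nrow(rep_) > 0L)
    validation_error(paste0(
      "invalid series '", s$patient_id, "': ",
      paste(rep_$message, collapse = "; ")))
  s
}

# Low-level constructor: computes gaps/segments, performs no validation.
new_vitals_series <- function(patient_id, t, map, hpi = NULL) {
  t <- as.numeric(t); map <- as.numeric(map)
  if (!is.null(hpi)) hpi <- as.numeric(hpi)
  d <- diff(t)
  gap_idx <- which(d > DT + EPS)
  gaps <- data.frame(start = t[gap_idx], end = t[gap_idx + 1L])
  segment <- cumsum(c(1L, as.integer(d > 60 + EPS)))
  structure(
    list(patient_id = as.character(patient_id), t = t, map = map, hpi = hpi,
         gaps = gaps, segment = segment),
    class = "vitals_series")
}

#' Validate a vitals series against its invariants
#'
#' Reports every invariant violation (non-increasing time, length mismatch,
#' non-finite or non-positive MAP, index outside `[0, 100]`) rather than
#' raising; an empty report means the series is valid.
#'
#' @param series A `vitals_series` (possibly malformed).
#' @return Data frame with columns `check`, `index`, `message`; zero rows iff
#'   all invariants hold.
#' @export
validate_series <- function(series) {
  out <- data.frame(check = character(), index = integer(), message = character())
  add <- function(check, index, message) {
    rbind(out, data.frame(check = check, index = as.integer(index), message = message))
  }
  t <- series$t; map <- series$map; hpi <- series$hpi
  if (length(t) != length(map))
    out <- add("length", NA, "t and map differ in length")
  if (!is.null(hpi) && length(hpi) != length(t))
    out <- add("length", NA, "hpi differs in length from t")
  bad_t <- which(diff(t) <= 0)
  for (i in bad_t)
    out <- add("time", i + 1L, sprintf("non-increasing time at sample %d", i + 1L))
  bad_map <- which(!is.finite(map) | map <= 0)
  for (i in bad_map)
    out <- add("map", i, sprintf("non-finite or non-positive MAP at sample %d", i))
  if (!is.null(hpi)) {
    bad_h <- which(!is.finite(hpi) | hpi < 0 | hpi > 100)
    for (i in bad_h)
      out <- add("hpi", i, sprintf("index outside [0, 100] at sample %d", i))
  }
  out
}

has_hpi <- function(series) !is.null(series$hpi)

n_samples <- function(series) length(series$t)

#' Record spans per evaluation segment
#'
#' The time interval each segment of a series covers, `[first sample,
#' last sample + 20)`, used to delimit non-alert periods in classification.
#'
#' @param series A [vitals_series()].
#' @return Data frame with `start`/`end` (seconds), one row per segment.
#' @export
record_spans <- function(series) {
  seg <- series$segment
  idx <- split(seq_along(seg), seg)
  data.frame(
    start = vapply(idx, function(i) series$t[i[1L]], numeric(1)),
    end   = vapply(idx, function(i) series$t[i[length(i)]] + DT, numeric(1)),
    row.names = NULL)
}

monitored_minutes <- function(series) n_samples(series) * DT / 60

#' Cohort of vitals series
#'
#' @param series List of `vitals_series` with unique patient ids.
#' @return Object of class `cohort`: a named list of series (names are the
#'   patient ids) with attribute `dropped` counting rows discarded on read.
#' @export
cohort <- function(series) {
  ids <- vapply(series, function(s) s$patient_id, character(1))
  if (anyDuplicated(ids))
    integrity_error(paste0("duplicate patient_id: ",
                           paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  names(series) <- ids
  structure(series, class = "cohort")
}

#' Read a cohort from a vitals CSV
#'
#' Expects a comma-separated UTF-8 file with header columns `patient_id`,
#' `time_s`, `map_mmhg` and optionally `hpi`. Rows may arrive unsorted; they
#' are ordered per patient by `time_s`. Rows with non-finite MAP are dropped
#' and counted in the `dropped` attribute of the result.
#'
#' @param path Path to the CSV file.
#' @return A [cohort()] with one `vitals_series` per patient.
#' @export
read_vitals_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "time_s", "map_mmhg")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    schema_error(paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  has_hpi_col <- "hpi" %in% names(df)
  if (has_hpi_col) {
    bad <- which(is.finite(df$hpi) & (df$hpi < 0 | df$hpi > 100))
    if (length(bad) > 0L)
      validation_error(sprintf("hpi outside [0,100] at row %d", bad[1L]), rows = bad)
  }
  keep <- is.finite(df$map_mmhg)
  dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  series <- lapply(split(df, df$patient_id), function(p) {
    p <- p[order(p$time_s), , drop = FALSE]
    if (anyDuplicated(p$time_s))
      integrity_error(sprintf("duplicate (patient_id, time_s) for patient '%s'",
                              p$patient_id[1L]))
    vitals_series(p$patient_id[1L], p$time_s, p$map_mmhg,
                  hpi = if (has_hpi_col) p$hpi else NULL)
  })
  co <- cohort(unname(series))
  attr(co, "dropped") <- dropped
  co
}

#' Write a cohort to a vitals CSV
#'
#' Inverse of [read_vitals_csv()]: writes the same schema
#' (`patient_id,time_s,map_mmhg[,hpi]`), including the `hpi` column iff every
#' series carries an index signal.
#'
#' @param cohort A [cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vitals_csv <- function(cohort, path) {
  all_hpi <- all(vapply(cohort, has_hpi, logical(1)))
  rows <- lapply(cohort, function(s) {
    d <- data.frame(patient_id = s$patient_id, time_s = s$t, map_mmhg = s$map)
    if (all_hpi) d$hpi <- s$hpi
    d
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.vitals_series <- function(x, ...) {
  cat(sprintf("<vitals_series> patient %s: %d samples, %.1f min%s, %d gap(s)\n",
              x$patient_id, n_samples(x), monitored_minutes(x),
              if (has_hpi(x)) ", with index" else "", nrow(x$gaps)))
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patient(s), %.0f monitored minutes total\n",
              length(x), sum(vapply(x, monitored_minutes, numeric(1)))))
  invisible(x)
}
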