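# Trace builders and independent brute-force oracles used across tests.
# The oracles deliberately re-derive the printed definitions by exhaustive
# enumeration, independent of the package's scanning implementations.

make_series <- function(map, hpi = NULL, t = NULL, id = "T") {
  if (is.null(t)) t <- (seq_along(map) - 1) * 20
  vitals_series(id, t, map, hpi = hpi)
}

# Brute-force event finder for regularly sampled traces: enumerate every
# index interval [i, j], test the printed definition directly, keep the
# maximal qualifying intervals.
oracle_detect_hypotension <- function(map, thr = 65) {
  n <- length(map)
  sub <- map < thr
  qualifies <- function(i, j) {
    if (!sub[i] || !sub[j]) return(FALSE)
    if (sum(sub[i:j]) * 20 < 60) return(FALSE)       # < 1 min below threshold
    # every internal normalised stretch must be < 1 min
    r <- rle(sub[i:j])
    if (any(!r$values & r$lengths * 20 >= 60)) return(FALSE)
    TRUE
  }
  maximal <- function(i, j) {
    # a sub-threshold sample within 60 s before i (or after j) would merge
    # into this event, so [i, j] would not be maximal
    left_clear <- i == 1 || !any(sub[max(1, i - 3):(i - 1)])
    right_clear <- j == n || !any(sub[(j + 1):min(n, j + 3)])
    left_clear && right_clear
  }
  out <- NULL
  for (i in seq_len(n)) for (j in i:n) {
    if (qualifies(i, j) && maximal(i, j)) {
      cand <- c(onset = (i - 1) * 20, end = (j - 1) * 20 + 20)
      out <- rbind(out, cand)
    }
  }
  if (is.null(out)) return(data.frame(onset_t = numeric(), end_t = numeric()))
  out <- as.data.frame(out)
  names(out) <- c("onset_t", "end_t")
  out <- unique(out[order(out$onset_t), , drop = FALSE])
  # among nested qualifying intervals keep the widest per onset
  keep <- !duplicated(out$onset_t)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force intervention detection over all sample pairs (regular 20-s
# grid), with an independent transitive-overlap collapse.
oracle_detect_interventions <- function(map) {
  n <- length(map)
  det <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    dt_s <- (j - i) * 20
    if (dt_s > 120) next
    if (map[i] >= 70) next
    delta <- map[j] - map[i]
    rule <- if (j == i + 1 && delta >= 5) "short"
            else if (delta >= 8) "long" else NA
    if (is.na(rule)) next
    det <- rbind(det, data.frame(t = (j - 1) * 20, rule = rule, delta = delta,
                                 baseline = map[i], window_start = (i - 1) * 20))
  }
  if (is.null(det)) return(det)
  # transitive closure of window overlap via repeated pairwise merging
  grp <- seq_len(nrow(det))
  repeat {
    changed <- FALSE
    for (a in seq_len(nrow(det))) for (b in seq_len(nrow(det))) {
      if (grp[a] != grp[b] &&
          det$window_start[a] < det$t[b] - 1e-9 &&
          det$window_start[b] < det$t[a] - 1e-9) {
        grp[grp == grp[b]] <- grp[a]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(split(det, grp), function(d) {
    d <- d[order(d$t, d$rule != "short", -d$delta), , drop = FALSE]
    d[1L, , drop = FALSE]
  }))
  out <- out[order(out$t), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Literal replay of the shift procedure for the extrapolation time-to-event,
# written over a lookup table rather than the series object.
oracle_lep_extension <- function(t, map, onset, n, max_lookback = 1200) {
  val <- function(time_s) {
    i <- which(abs(t - time_s) < 1e-9)
    if (length(i) == 0L) NA_real_ else map[i]
  }
  preds <- c()
  x <- 0
  repeat {
    h <- n + x
    if (h > max_lookback) break
    a <- val(onset - h); b <- val(onset - h - n)
    if (is.na(a) || is.na(b)) break
    preds <- c(preds, a + (h / n) * (a - b))
    x <- x + 20
  }
  if (length(preds) == 0L || preds[1L] >= 65) return(NA_real_)
  n_ok <- which(preds >= 65)
  k <- if (length(n_ok) == 0L) length(preds) else n_ok[1L] - 1L
  n + (k - 1L) * 20
}

# Random 30-sample trace in the hypotension-boundary MAP range.
random_boundary_trace <- function() {
  round(stats::runif(30, 55, 85), 1)
}

# A tiny simulated patient for structural property tests.
quick_patient <- function(seed, n_patients = 1) {
  simulate_patient(sim_config(), seed, sprintf("Q%d", seed))
}
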