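# Internal helpers shared across modules.

# Nominal sampling interval of the monitor export (seconds).
DT <- 20
EPS <- 1e-9

stop_hypoalert <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "hypoalert_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

schema_error     <- function(msg, ...) stop_hypoalert("hypoalert_schema_error", msg, ...)
integrity_error  <- function(msg, ...) stop_hypoalert("hypoalert_integrity_error", msg, ...)
validation_error <- function(msg, ...) stop_hypoalert("hypoalert_validation_error", msg, ...)
capability_error <- function(msg, ...) stop_hypoalert("hypoalert_capability_error", msg, ...)
config_error     <- function(msg, ...) stop_hypoalert("hypoalert_config_error", msg, ...)

# Run RNG-dependent code under `seed` without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Maximal runs of TRUE in `x`, broken wherever `brk` is TRUE between
# neighbours (brk[i] refers to the transition i -> i+1).
true_runs <- function(x, brk = NULL) {
  n <- length(x)
  if (n == 0L || !any(x)) return(data.frame(start = integer(), end = integer()))
  if (is.null(brk)) brk <- rep(FALSE, max(n - 1L, 0L))
  starts <- integer(); ends <- integer()
  i <- 1L
  while (i <= n) {
    if (x[i]) {
      j <- i
      while (j < n && x[j + 1L] && !brk[j]) j <- j + 1L
      starts <- c(starts, i); ends <- c(ends, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  data.frame(start = starts, end = ends)
}

# Subtract closed-open intervals `cut` (start,end) from intervals `from`,
# returning the remaining maximal pieces. All data.frames with start/end.
interval_subtract <- function(from, cut) {
  if (nrow(from) == 0L) return(from[, c("start", "end")])
  if (is.null(cut) || nrow(cut) == 0L)
    return(data.frame(start = from$start, end = from$end))
  cut <- cut[order(cut$start), , drop = FALSE]
  out_s <- numeric(); out_e <- numeric()
  for (k in seq_len(nrow(from))) {
    s <- from$start[k]; e <- from$end[k]
    for (j in seq_len(nrow(cut))) {
      cs <- cut$start[j]; ce <- cut$end[j]
      if (ce <= s + EPS || cs >= e - EPS) next
      if (cs > s + EPS) { out_s <- c(out_s, s); out_e <- c(out_e, min(cs, e)) }
      s <- max(s, ce)
      if (s >= e - EPS) break
    }
    if (s < e - EPS) { out_s <- c(out_s, s); out_e <- c(out_e, e) }
  }
  data.frame(start = out_s, end = out_e)
}

# Quantile convention used for all interval summaries.
q25 <- function(x) unname(stats::quantile(x, 0.25, type = 7, na.rm = TRUE))
q75 <- function(x) unname(stats::quantile(x, 0.75, type = 7, na.rm = TRUE))
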