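# Minimal hand-built scenarios use raw episode/event frames; full-trace
# scenarios come from the simulator.

episode_frame <- function(start, end, id = "p") {
  data.frame(predictor_id = id, start_t = start, qualify_t = start,
             end_t = end, censored = FALSE,
             n_samples = as.integer((end - start) / 20))
}
event_frame <- function(onset, end) {
  data.frame(onset_t = onset, end_t = end, duration = end - onset,
             n_sub = as.integer((end - onset) / 20),
             sub_time_s = end - onset)
}
span <- function(end, start = 0) data.frame(start = start, end = end)

test_that("an alert active until onset is a true positive with its lead time", {
  cs <- classify_adjacency(episode_frame(100, 200), event_frame(200, 400),
                           NULL, span(1200))
  ep <- cs$items[cs$items$kind == "alert-episode", ]
  expect_equal(ep$label, "TP")
  expect_equal(ep$tte, 100)
  expect_equal(cs$event_match$tte, 100)
})

test_that("an alert fading before onset is FP and the gap period FN", {
  cs <- classify_adjacency(episode_frame(100, 160), event_frame(200, 400),
                           NULL, span(1200))
  it <- cs$items
  expect_equal(it$label[it$kind == "alert-episode"], "FP")
  gap <- it[it$kind == "non-alert-period" & it$start_t == 160, ]
  expect_equal(gap$label, "FN")
  expect_equal(gap$end_t, 200)
  expect_true(all(it$label[it$kind == "non-alert-period" & it$start_t != 160] == "TN"))
  expect_true(is.na(cs$event_match$tte))
})

test_that("episodes containing an intervention mark are excluded, not FP", {
  marks <- data.frame(t = 150, rule = "short", delta = 6, baseline = 68,
                      window_start = 130)
  cs <- classify_adjacency(episode_frame(100, 200), data.frame(event_frame(1, 1))[0, ],
                           marks, span(1200))
  expect_equal(cs$items$label[cs$items$kind == "alert-episode"], "EXCLUDED")
  # the same episode without the mark is FP
  cs2 <- classify_adjacency(episode_frame(100, 200), data.frame(event_frame(1, 1))[0, ],
                            NULL, span(1200))
  expect_equal(cs2$items$label[cs2$items$kind == "alert-episode"], "FP")
})

test_that("overlapping episodes of one predictor are an integrity error", {
  eps <- rbind(episode_frame(100, 200), episode_frame(180, 260))
  expect_error(classify_adjacency(eps, event_frame(400, 500), NULL, span(1200)),
               class = "hypoalert_integrity_error")
})

test_that("timeframe classification credits alerts that fade before the event", {
  # episode fades 5 min before an onset 12 min after its start
  cs <- classify_timeframe(episode_frame(0, 420), event_frame(720, 900),
                           NULL, span(2400))
  ep <- cs$items[cs$items$kind == "alert-episode", ]
  expect_equal(ep$label, "TP")
  expect_equal(ep$tte, 720)
  # no onset within 20 min -> FP
  cs2 <- classify_timeframe(episode_frame(0, 420), event_frame(1800, 1900),
                            NULL, span(2400))
  expect_equal(cs2$items$label[cs2$items$kind == "alert-episode"], "FP")
  expect_error(classify_timeframe(episode_frame(0, 420), event_frame(720, 900),
                                  NULL, span(2400), window = 0),
               class = "hypoalert_config_error")
})

test_that("initial non-alerts before a later alert are discarded, not FN", {
  # non-alert at t = 0, alert begins at 300 s, onset at 600 s
  cs <- classify_timeframe(episode_frame(300, 420), event_frame(600, 780),
                           NULL, span(2400))
  it <- cs$items
  expect_equal(it$label[it$kind == "alert-episode"], "TP")
  first_gap <- it[it$kind == "non-alert-period" & it$start_t == 0, ]
  expect_equal(first_gap$label, "DISCARDED")
})

test_that("onset exactly at an episode start is not a prediction", {
  cs <- classify_timeframe(episode_frame(600, 700), event_frame(600, 780),
                           NULL, span(2400))
  expect_equal(cs$items$label[cs$items$kind == "alert-episode"], "FP")
})

test_that("every episode receives exactly one of TP/FP/EXCLUDED", {
  set.seed(407)
  for (rep in 1:40) {
    n_ep <- sample(0:6, 1)
    starts <- sort(sample(seq(0, 2000, by = 20), n_ep))
    eps <- do.call(rbind, lapply(starts, function(s0)
      episode_frame(s0, s0 + 20 * sample(1:5, 1))))
    if (is.null(eps)) eps <- episode_frame(0, 20)[0, ]
    # keep episodes disjoint
    if (nrow(eps) > 1) {
      keep <- c(TRUE, eps$start_t[-1] >= cummax(eps$end_t[-nrow(eps)]))
      eps <- eps[keep, , drop = FALSE]
    }
    evs <- event_frame(2200, 2400)
    marks <- if (stats::runif(1) < 0.5)
      data.frame(t = sample(seq(0, 2400, 20), 1), rule = "short", delta = 6,
                 baseline = 68, window_start = 0) else NULL
    for (cs in list(classify_adjacency(eps, evs, marks, span(2600)),
                    classify_timeframe(eps, evs, marks, span(2600)))) {
      lab <- cs$items$label[cs$items$kind == "alert-episode"]
      expect_equal(length(lab), nrow(eps))
      expect_true(all(lab %in% c("TP", "FP", "EXCLUDED")))
    }
  }
})

test_that("an oracle predictor alerting [onset-k, onset) recovers every event exactly", {
  set.seed(408)
  k <- 120
  for (seed in 1:6) {
    s <- quick_patient(seed)$series
    ev <- detect_hypotension(s)
    if (nrow(ev) == 0) next
    # an oracle alert needs k clear seconds before its event
    clear <- ev$onset_t - k >= c(0, ev$end_t[-nrow(ev)])
    eps <- do.call(rbind, lapply(ev$onset_t[clear], function(o)
      episode_frame(o - k, o)))
    cs <- classify_adjacency(eps, ev, NULL, record_spans(s))
    epit <- cs$items[cs$items$kind == "alert-episode", ]
    expect_true(all(epit$label == "TP"))
    expect_true(all(epit$tte == k))
    expect_equal(sum(!is.na(cs$event_match$tte)), nrow(eps))
    if (all(clear)) {
      # non-alert periods abutting onsets are covered by the oracle alerts
      expect_true(all(cs$items$label[cs$items$kind == "non-alert-period"] == "TN"))
    }
  }
})

test_that("adjacency true positives are a subset of timeframe true positives", {
  set.seed(409)
  for (seed in 1:10) {
    s <- quick_patient(seed)$series
    ev <- detect_hypotension(s)
    iv <- detect_interventions(s)
    sp <- record_spans(s)
    for (thr in c(70, 73)) {
      eps <- threshold_episodes(s, alert_definition("m", "MAP", thr),
                                event_mask(ev))
      adj <- classify_adjacency(eps, ev, iv, sp)
      win <- max(1200, adj$items$tte, na.rm = TRUE)
      tfr <- classify_timeframe(eps, ev, iv, sp, window = win)
      tp_adj <- adj$items$start_t[adj$items$label == "TP"]
      tp_tfr <- tfr$items$start_t[tfr$items$label == "TP"]
      expect_true(all(tp_adj %in% tp_tfr))
    }
  }
})

test_that("a MAP alert above 65 is active at onset for monotone declines", {
  map <- c(seq(80, 64, by = -1), rep(63, 3), rep(70, 4))
  s <- make_series(map)
  ev <- detect_hypotension(s)
  expect_equal(nrow(ev), 1L)
  for (thr in 70:75) {
    eps <- threshold_episodes(s, alert_definition("m", "MAP", thr),
                              event_mask(ev))
    cs <- classify_adjacency(eps, ev, NULL, record_spans(s))
    expect_true(any(cs$items$label == "TP"))
  }
})
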