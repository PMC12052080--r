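# Hand-built classified sets: one patient trace with controllable outcomes.
episode_frame2 <- function(start, end) {
  data.frame(predictor_id = "p", start_t = start, qualify_t = start,
             end_t = end, censored = FALSE,
             n_samples = as.integer((end - start) / 20))
}
event_frame2 <- function(onset, end) {
  data.frame(onset_t = onset, end_t = end, duration = end - onset,
             n_sub = as.integer((end - onset) / 20), sub_time_s = end - onset)
}

# Scenario: two events at 1000 and 3000, predicted with lead `lead` seconds;
# plus `n_fp` stray episodes. Returns (classified_set, events).
scenario <- function(lead = 120, n_fp = 0, span_end = 6000) {
  evs <- rbind(event_frame2(1000, 1200), event_frame2(3000, 3200))
  eps <- rbind(episode_frame2(1000 - lead, 1000), episode_frame2(3000 - lead, 3000))
  if (n_fp > 0)
    for (i in seq_len(n_fp))
      eps <- rbind(eps, episode_frame2(4000 + i * 200, 4100 + i * 200))
  cs <- classify_adjacency(eps, evs, NULL, data.frame(start = 0, end = span_end))
  list(cs = cs, evs = evs)
}

test_that("pooled counts give the predictive values and missed rate", {
  sc <- scenario(lead = 120, n_fp = 2)
  rep_ <- summarize_predictor(list(sc$cs), list(sc$evs), bootstrap_config(100, 1))
  expect_equal(rep_$point[["ppv"]], 50)          # 2 TP, 2 FP
  expect_equal(rep_$point[["missed_median"]], 0)
  expect_equal(rep_$point[["tte_min"]], 2)
  expect_equal(rep_$point[["npv"]], 100)         # all non-alert periods TN
  expect_equal(unname(rep_$counts[c("tp", "fp")]), c(2, 2))
})

test_that("a predictor with no alerts reports PPV as not available", {
  evs <- event_frame2(1000, 1200)
  cs <- classify_adjacency(episode_frame2(0, 20)[0, ], evs, NULL,
                           data.frame(start = 0, end = 3000))
  rep_ <- summarize_predictor(list(cs), list(evs), bootstrap_config(50, 1))
  expect_true(is.na(rep_$point[["ppv"]]))
  expect_equal(rep_$point[["missed_median"]], 100)
})

test_that("the bootstrap is bit-reproducible and degenerate cohorts have zero-width CIs", {
  sc <- scenario(lead = 120, n_fp = 3)
  cls <- rep(list(sc$cs), 5)
  evs <- rep(list(sc$evs), 5)
  r1 <- summarize_predictor(cls, evs, bootstrap_config(200, 11))
  r2 <- summarize_predictor(cls, evs, bootstrap_config(200, 11))
  expect_identical(r1, r2)
  # identical patients: every resample pools the same proportions
  expect_equal(r1$ci_lo, r1$ci_hi)
  expect_equal(unname(r1$ci_lo[["ppv"]]), 40)
  # heterogeneous cohort: the resample stream depends on the seed
  scs <- lapply(c(60, 120, 180, 240), function(l) scenario(lead = l, n_fp = l / 60))
  het_cls <- lapply(scs, `[[`, "cs"); het_evs <- lapply(scs, `[[`, "evs")
  h1 <- summarize_predictor(het_cls, het_evs, bootstrap_config(200, 11))
  h3 <- summarize_predictor(het_cls, het_evs, bootstrap_config(200, 12))
  expect_false(identical(h1$boot_mean, h3$boot_mean))
})

test_that("pooled PPV is invariant under patient relabelling", {
  set.seed(410)
  scs <- lapply(c(60, 120, 180, 240), function(l) scenario(lead = l, n_fp = l / 60))
  cls <- lapply(scs, `[[`, "cs"); evs <- lapply(scs, `[[`, "evs")
  base <- summarize_predictor(cls, evs, bootstrap_config(50, 3))
  perm <- sample(length(cls))
  shuf <- summarize_predictor(cls[perm], evs[perm], bootstrap_config(50, 3))
  expect_equal(base$point, shuf$point)
  expect_equal(base$counts, shuf$counts)
})

test_that("paired gains follow the all-events convention with missed as zero", {
  a <- scenario(lead = 120)$cs   # alerts 2 min ahead
  b <- scenario(lead = 60)$cs    # alerts 1 min ahead
  g <- paired_time_gain(list(a), list(b), bootstrap_config(100, 2))
  expect_equal(g$gains, c(1, 1))
  expect_equal(g$mean_gain_min, 1)
  # B misses both events entirely
  evs <- rbind(event_frame2(1000, 1200), event_frame2(3000, 3200))
  miss <- classify_adjacency(episode_frame2(0, 20)[0, ], evs, NULL,
                             data.frame(start = 0, end = 6000))
  g2 <- paired_time_gain(list(a), list(miss), bootstrap_config(100, 2))
  expect_equal(g2$gains, c(2, 2))
  # identity comparison: all gains zero, CI (0, 0)
  g3 <- paired_time_gain(list(a), list(a), bootstrap_config(100, 2))
  expect_equal(g3$gains, c(0, 0))
  expect_equal(g3$ci_lo, 0)
  expect_equal(g3$ci_hi, 0)
  # antisymmetry
  g4 <- paired_time_gain(list(b), list(a), bootstrap_config(100, 2))
  expect_equal(g4$gains, -g$gains)
})

test_that("paired gains require identical event lists", {
  a <- scenario(lead = 120)$cs
  other <- classify_adjacency(episode_frame2(0, 20)[0, ], event_frame2(500, 700),
                              NULL, data.frame(start = 0, end = 6000))
  expect_error(paired_time_gain(list(a), list(other)),
               class = "hypoalert_integrity_error")
})

test_that("confidence interval width shrinks roughly as one over root patients", {
  set.seed(411)
  widths <- vapply(c(8, 32, 128), function(n) {
    leads <- 20 * sample(3:12, n, replace = TRUE)
    scs <- lapply(leads, function(l) scenario(lead = l, n_fp = 1))
    r <- summarize_predictor(lapply(scs, `[[`, "cs"), lapply(scs, `[[`, "evs"),
                             bootstrap_config(300, 5))
    r$ci_hi[["tte_min"]] - r$ci_lo[["tte_min"]]
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(widths) ~ log(c(8, 32, 128))))[2]
  expect_gt(slope, -0.7)
  expect_lt(slope, -0.3)
})

test_that("the MAP distribution per index value reflects the index-MAP link", {
  maps <- seq(40, 100, by = 1)
  s1 <- make_series(maps, hpi = 100 - maps, id = "A")
  co1 <- cohort(list(s1))
  tab <- hpi_map_distribution(co1)
  expect_true(all(tab$map_min == tab$map_max))   # deterministic mapping
  expect_equal(tab$map_median, 100 - tab$hpi)
  s2 <- make_series(maps + 5, hpi = 100 - maps, id = "B")
  tab2 <- hpi_map_distribution(cohort(list(s1, s2)))
  expect_true(all(tab2$map_max - tab2$map_min == 5))
})

test_that("samples inside events and around interventions are excluded from the index table", {
  maps <- c(80, 75, 60, 60, 60, 75, 80, 80, 80, 80)
  s <- make_series(maps, hpi = 100 - maps, id = "A")
  co <- cohort(list(s))
  full <- hpi_map_distribution(co)
  ev <- detect_hypotension(s)
  masked <- hpi_map_distribution(co, events_by_patient = list(A = ev))
  expect_equal(sum(full$n) - sum(masked$n), 3L)
  expect_false(40 %in% masked$hpi)  # the in-event samples (hpi 40) are gone
  # interventions mask a +/- 2 min window
  iv <- data.frame(t = 120, rule = "short", delta = 6, baseline = 60,
                   window_start = 100)
  iv_masked <- hpi_map_distribution(co, interventions_by_patient = list(A = iv))
  expect_equal(sum(iv_masked$n), sum(full$n) - sum(abs(s$t - 120) <= 120))
})

test_that("rank correlation is -1 for a monotone index and ~0 for noise", {
  maps <- seq(50, 95, by = 0.5)
  s <- make_series(maps, hpi = 100 - maps, id = "A")
  expect_equal(spearman_hpi_map(cohort(list(s))), -1)
  set.seed(412)
  s2 <- make_series(stats::runif(2000, 60, 90),
                    hpi = stats::runif(2000, 0, 100), id = "B")
  expect_lt(abs(spearman_hpi_map(cohort(list(s2)))), 0.08)
  tiny <- make_series(c(70, 71), hpi = c(10, 20), id = "C")
  expect_true(is.na(spearman_hpi_map(cohort(list(tiny)))))
})

test_that("masking a monotone-breaking outlier restores perfect correlation", {
  maps <- c(90, 85, 80, 95)
  hpis <- c(10, 20, 30, 40)  # last pair breaks monotonicity
  s <- make_series(maps, hpi = hpis, id = "A")
  co <- cohort(list(s))
  expect_gt(spearman_hpi_map(co), -1)
  iv <- data.frame(t = 60, rule = "short", delta = 15, baseline = 60,
                   window_start = 40)
  rho <- spearman_hpi_map(co, interventions_by_patient = list(A = iv),
                          outlier_window = 10)
  expect_equal(rho, -1)
})
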