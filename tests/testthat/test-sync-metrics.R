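test_that("aggregate_stats matches brute-force formulas and conventions", {
  # published-style per-cycle on-deltas: population SD rounds to 0.04,
  # sample SD would round to 0.05
  x <- c(-0.01, 0.10, 0.04, 0.01, -0.02)
  st <- aggregate_stats(x)
  expect_equal(round_half_up(st$mean), 0.02)
  expect_equal(round_half_up(st$sd), 0.04)
  expect_equal(round_half_up(st$median), 0.01)
  expect_equal(round_half_up(aggregate_stats(x, "sample")$sd), 0.05)

  expect_equal(unlist(aggregate_stats(0.07)[c("mean", "sd", "median")]),
               c(mean = 0.07, sd = 0, median = 0.07))

  set.seed(17)
  for (rep in 1:100) {
    v <- rnorm(sample(1:30, 1))
    st <- aggregate_stats(v)
    o <- oracle_stats(v)
    expect_equal(st$mean, unname(o["mean"]))
    expect_equal(st$sd, unname(o["sd"]))
    expect_equal(st$median, unname(o["median"]))
    expect_equal(st$n, length(v))
    # median invariant under permutation
    expect_equal(aggregate_stats(sample(v))$median, st$median)
  }

  expect_error(aggregate_stats(numeric()), class = "gatelog_empty_input_error")
  expect_error(aggregate_stats(c(1, NA)), class = "gatelog_parameter_error")
})

test_that("reporting rounds half away from zero, internals stay full precision", {
  expect_equal(round_half_up(c(0.045, -0.045, 0.135, -0.135)),
               c(0.05, -0.05, 0.14, -0.14))
  expect_equal(aggregate_stats(c(0.045, 0.045))$mean, 0.045)
})

test_that("pairing assigns intervals to the most-overlapped window", {
  cy <- tibble::tibble(index = 0L, t_start = 0, t_end = 4, period = 4)
  iv <- tibble::tibble(t_on = 1.03, t_off = 2.96, duration = 1.93,
                       complete = TRUE, leading_edge_seen = TRUE)
  rec <- pair_cycles_intervals(cy, iv)
  expect_equal(rec$delta_on, 0.03)
  expect_equal(rec$delta_off, -0.04)
  expect_equal(rec$window_duration, 2)
  expect_equal(rec$trigger_duration, 1.93)
  # sign/duration algebraic identity
  expect_equal(rec$delta_on - rec$delta_off,
               rec$window_duration - rec$trigger_duration)
})

test_that("unmatched cycles and intervals are reported, not dropped", {
  cy <- tibble::tibble(index = 0:1, t_start = c(0, 4), t_end = c(4, 8),
                       period = 4)
  iv <- tibble::tibble(t_on = 5.1, t_off = 6.9, duration = 1.8,
                       complete = TRUE, leading_edge_seen = TRUE)
  rec <- pair_cycles_intervals(cy, iv)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$cycle_index, 1)
  expect_equal(attr(rec, "unmatched_cycles"), 0)
  expect_length(attr(rec, "unmatched_intervals"), 0)

  none <- tibble::tibble(t_on = 20, t_off = 21, duration = 1,
                         complete = TRUE, leading_edge_seen = TRUE)
  expect_error(pair_cycles_intervals(cy, none),
               class = "gatelog_pairing_error")
})

test_that("a simulated session pairs bijectively with the identity holding per record", {
  log <- sim_session(latency_on = 0.05, latency_off = 0.05, seed = 9)
  s <- analyze_gating_session(log)
  expect_equal(nrow(s$records), 5) # 6 periods -> 5 complete cycles
  expect_equal(s$records$cycle_index, 0:4)
  expect_length(attr(s$records, "unmatched_cycles"), 0)
  expect_equal(s$records$delta_on - s$records$delta_off,
               s$records$window_duration - s$records$trigger_duration,
               tolerance = 1e-9)
})

test_that("injected latencies are recovered by the full pipeline", {
  for (L in c(0, 0.03, 0.05, 0.10)) {
    log <- sim_session(latency_on = L, latency_off = L, seed = 31)
    g <- glance(analyze_gating_session(log))
    expect_true(abs(g$delta_on_mean - L) <= 0.04 + 1e-9,
                info = paste("on-latency", L))
    expect_true(abs(g$delta_off_mean - L) <= 0.04 + 1e-9,
                info = paste("off-latency", L))
    # equal latencies shift both edges: duration gap stays ~0
    expect_true(abs(g$duration_gap) <= 0.04 + 1e-9)
  }
})

test_that("duration comparison aggregates per-cycle window minus trigger gaps", {
  rec <- tibble::tibble(
    cycle_index = 0:2, t25 = c(1, 5, 9), t75 = c(3.66, 7.66, 11.66),
    t_on = c(1, 5, 9) + 0.02, t_off = c(3.66, 7.66, 11.66) - 0.03,
    delta_on = 0.02, delta_off = -0.03,
    window_duration = 2.66, trigger_duration = 2.61
  )
  s <- session_result(rec, "fx")
  gap <- duration_comparison(s)
  expect_equal(gap$mean, 0.05)
  expect_equal(gap$sd, 0)
  expect_equal(s$duration_gap, 0.05)

  rec_eq <- dplyr::mutate(rec, t_on = t25, t_off = t75,
                          trigger_duration = window_duration,
                          delta_on = 0, delta_off = 0)
  expect_equal(duration_comparison(session_result(rec_eq, "fx"))$mean, 0)
})

test_that("dose comparison handles paired and unpaired modes", {
  d <- dose_comparison(c(100, 100), c(100.1, 99.9))
  diff_row <- d[d$arm == "difference", ]
  expect_equal(diff_row$mean, 0)
  expect_equal(diff_row$sd, 0.1)
  expect_equal(attr(d, "paired_diffs"), c(0.1, -0.1))

  same <- dose_comparison(c(99.9, 100.2), c(99.9, 100.2))
  expect_equal(same$mean[same$arm == "difference"], 0)
  expect_equal(same$sd[same$arm == "difference"], 0)

  up <- dose_comparison(c(100, 100, 100), c(99.9, 100.1), paired = FALSE)
  expect_false("difference" %in% up$arm)
  expect_equal(up$n, c(3, 2))

  expect_error(dose_comparison(c(100, 100), c(100), paired = TRUE),
               class = "gatelog_parameter_error")
  expect_error(dose_comparison(c(-1, 100), c(100, 100)),
               class = "gatelog_parameter_error")
})

test_that("reproducibility trend tabulates sessions and their drift", {
  mk <- function(id, trig) {
    rec <- tibble::tibble(
      cycle_index = 0:4, t25 = 1:5, t75 = (1:5) + 2.66,
      t_on = (1:5) + 0.02, t_off = (1:5) + 0.02 + trig,
      delta_on = 0.02, delta_off = (1:5) * 0 + 0.02 + trig - 2.66,
      window_duration = 2.66, trigger_duration = trig
    )
    session_result(rec, id)
  }
  tr <- reproducibility_trend(list(mk("m1", 2.60), mk("m2", 2.60), mk("m3", 2.59)))
  drift <- tr$drift$max_abs_drift[tr$drift$metric == "trigger_duration"]
  expect_equal(drift, 0.01)

  same <- reproducibility_trend(list(mk("a", 2.6), mk("b", 2.6), mk("c", 2.6)))
  expect_true(all(same$drift$max_abs_drift < 1e-12))

  # identical seeds give identical rows end-to-end
  s1 <- analyze_gating_session(sim_session(seed = 5, noise_sd = 0.02))
  s2 <- analyze_gating_session(sim_session(seed = 5, noise_sd = 0.02))
  s1$session_id <- "run1"; s2$session_id <- "run2"
  tr2 <- reproducibility_trend(list(s1, s2))
  rows <- split(dplyr::select(tr2$per_session, -"session_id"),
                tr2$per_session$session_id)
  expect_equal(rows[[1]], rows[[2]], ignore_attr = TRUE)
})

test_that("tidiers expose records and one-row summaries", {
  s <- analyze_gating_session(sim_session(seed = 2))
  td <- tidy(s)
  expect_true(all(c("session_id", "cycle_index", "delta_on") %in% names(td)))
  g <- glance(s)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_cycles, nrow(s$records))
})
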