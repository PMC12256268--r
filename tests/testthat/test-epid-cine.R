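make_stack <- function(levels, rows = 32, cols = 32, fp = 0.04,
                       noise_sd = 0, seed = NULL) {
  n <- length(levels)
  frames <- array(rep(levels, each = rows * cols), dim = c(rows, cols, n))
  if (noise_sd > 0) {
    set.seed(seed)
    frames <- frames + array(rnorm(length(frames), 0, noise_sd),
                             dim = dim(frames))
  }
  gatelog:::new_epid_stack(frames, (seq_len(n) - 1) * fp, fp,
                           pixel_spacing_cm = 0.3, sid_cm = 150, sad_cm = 100)
}

test_that("ROI means equal a brute-force pixel loop on random frames", {
  set.seed(23)
  for (rep in 1:100) {
    n <- sample(3:8, 1)
    frames <- array(runif(32 * 32 * n, 0, 100), dim = c(32, 32, n))
    stack <- gatelog:::new_epid_stack(frames, (seq_len(n) - 1) * 0.04, 0.04,
                                      0.3, 150, 100)
    roi <- roi_spec(side_cm_at_iso = 3) # 15 px projected
    ser <- compute_roi_series(stack, roi)
    side_px <- round(3 * 1.5 / 0.3)
    half <- (side_px - 1) / 2
    rows <- round(16.5 - half):round(16.5 + half)
    expected <- vapply(seq_len(n), function(k) {
      acc <- 0
      for (i in rows) for (j in rows) acc <- acc + frames[i, j, k]
      acc / (length(rows)^2)
    }, numeric(1))
    expect_equal(ser$roi_mean, expected, info = paste("rep", rep))
    expect_equal(ser$roi_mean_norm, expected / max(expected))
  }
})

test_that("constant frames give norm 1 everywhere; one bright frame a single 1", {
  flat <- make_stack(rep(7, 5))
  ser <- compute_roi_series(flat)
  expect_equal(ser$roi_mean, rep(7, 5))
  expect_equal(ser$roi_mean_norm, rep(1, 5))

  spike <- compute_roi_series(make_stack(c(1, 1, 50, 1, 1)))
  expect_equal(sum(spike$roi_mean_norm == 1), 1)
  expect_equal(which(spike$roi_mean_norm == 1), 3)
})

test_that("an oversized ROI is rejected", {
  stack <- make_stack(rep(1, 3), rows = 8, cols = 8)
  expect_error(compute_roi_series(stack, roi_spec(side_cm_at_iso = 5)),
               class = "gatelog_parameter_error")
})

test_that("thresholding is strict and segments contiguous runs", {
  lv <- c(0.01, 0.02, 0.6, 0.9, 1.0, 0.95, 0.7, 0.3, 0.02, 0.01)
  ser <- compute_roi_series(make_stack(lv * 100))
  det <- detect_beam_on_frames(ser, 0.5)
  expect_equal(sum(det$on), 5)
  expect_equal(det$segments$start_frame, 2)
  expect_equal(det$segments$end_frame, 6)
  expect_equal(det$segments$n_frames, 5)

  # a frame exactly at the threshold counts as off
  exact <- compute_roi_series(make_stack(c(10, 50, 100, 50, 10)))
  expect_equal(sum(detect_beam_on_frames(exact, 0.5)$on), 1)

  none <- detect_beam_on_frames(ser, 1.0)
  expect_equal(nrow(none$segments), 0)
})

test_that("raising the threshold never increases the on-frame count", {
  set.seed(29)
  ser <- compute_roi_series(make_stack(runif(40, 0, 100)))
  counts <- vapply(c(0.3, 0.5, 0.7),
                   function(th) sum(detect_beam_on_frames(ser, th)$on),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("durations are frame counts times the frame period", {
  seg5 <- tibble::tibble(segment = 1L, start_frame = 0, end_frame = 4,
                         n_frames = 5L)
  expect_equal(epid_beam_durations(seg5, 0.04)$durations, 0.20)
  seg66 <- tibble::tibble(segment = 1L, start_frame = 0, end_frame = 65,
                          n_frames = 66L)
  d66 <- epid_beam_durations(seg66, 0.04)
  expect_equal(d66$durations, 2.64)
  expect_equal(d66$stats$mean, 2.64)

  empty <- epid_beam_durations(seg5[0, ], 0.04)
  expect_length(empty$durations, 0)
  expect_null(empty$stats)
})

test_that("simulated stacks recover the true on-windows within quantization", {
  cfg <- sim_config(latency_on_s = 0.05, latency_off_s = 0.05, seed = 3)
  log <- sim_session(latency_on = 0.05, latency_off = 0.05, seed = 3)
  stack <- simulate_epid_cine(log, cfg)
  ser <- compute_roi_series(stack)
  det <- detect_beam_on_frames(ser)
  dur <- epid_beam_durations(det$segments, stack$frame_period)
  truth <- attr(log, "truth")
  expect_equal(length(dur$durations), nrow(truth))
  true_dur <- truth$t_off_true - truth$t_on_true
  expect_true(all(abs(dur$durations - true_dur) <= stack$frame_period + 1e-9))
  # quantization: exact multiples of the frame period
  expect_equal(dur$durations, round(dur$durations / 0.04) * 0.04,
               tolerance = 1e-9)
})

test_that("persistence adds at most one recovered frame per segment", {
  cfg0 <- sim_config(seed = 4)
  cfgp <- sim_config(epid_persistence_frames = 1, seed = 4)
  log <- sim_session(seed = 4)
  d0 <- epid_beam_durations(
    detect_beam_on_frames(compute_roi_series(simulate_epid_cine(log, cfg0)))$segments)
  dp <- epid_beam_durations(
    detect_beam_on_frames(compute_roi_series(simulate_epid_cine(log, cfgp)))$segments)
  expect_true(all(dp$durations - d0$durations <= 0.04 + 1e-9))
  expect_true(all(dp$durations - d0$durations >= 0))
})

test_that("stacks round-trip through the on-disk fixture format", {
  cfg <- sim_config(epid_noise_sd = 0.02, seed = 8)
  log <- sim_session(seed = 8, noise_sd = 0)
  stack <- simulate_epid_cine(log, cfg)
  dir <- tempfile()
  write_epid_stack(stack, dir)
  back <- load_cine_frames(dir)
  expect_equal(dim(back$frames), dim(stack$frames))
  expect_equal(back$frame_times, stack$frame_times)
  expect_equal(back$frame_period, stack$frame_period)
  expect_true(max(abs(back$frames - stack$frames)) < 1e-6)
  expect_equal(back$sid_cm, stack$sid_cm)
})

test_that("missing sidecar geometry falls back to configured values", {
  cfg <- sim_config(seed = 6)
  stack <- simulate_epid_cine(sim_session(seed = 6), cfg)
  dir <- tempfile()
  write_epid_stack(stack, dir)
  meta <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                              simplifyVector = TRUE)
  meta$sid_cm <- NULL
  jsonlite::write_json(meta, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_message(back <- load_cine_frames(dir, sid_cm = 150), "SID")
  expect_equal(back$sid_cm, 150)
  expect_error(load_cine_frames(dir), class = "gatelog_configuration_error")
})

test_that("EPID and log durations agree within combined quantization", {
  cfg <- sim_config(latency_on_s = 0.03, latency_off_s = 0.03, seed = 12)
  log <- sim_session(latency_on = 0.03, latency_off = 0.03, seed = 12)
  s <- analyze_gating_session(log)
  stack <- simulate_epid_cine(log, cfg)
  dur <- epid_beam_durations(
    detect_beam_on_frames(compute_roi_series(stack))$segments,
    stack$frame_period)
  log_dur <- s$intervals$duration[s$intervals$complete]
  cmp <- compare_epid_vs_log(dur$durations, log_dur)
  expect_true(abs(cmp$mean) <= 0.04 + 0.04 + 1e-9)

  ident <- compare_epid_vs_log(c(2.64, 2.64), c(2.64, 2.64))
  expect_equal(ident$mean, 0)
  expect_equal(compare_epid_vs_log(2.64, 2.61)$mean, 0.03)
  expect_error(compare_epid_vs_log(numeric(), 1),
               class = "gatelog_empty_input_error")
})

test_that("the optional median filter suppresses salt noise in the ROI mean", {
  lv <- rep(10, 5)
  stack <- make_stack(lv)
  stack$frames[16, 16, 3] <- 1e5 # single hot pixel
  ser_raw <- compute_roi_series(stack)
  ser_med <- compute_roi_series(stack, median_filter = TRUE)
  expect_gt(ser_raw$roi_mean[3], 10)
  expect_equal(ser_med$roi_mean[3], 10, tolerance = 1e-9)
})
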