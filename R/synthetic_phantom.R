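# Virtual motion phantom: periodic AP motion, gated beam flags with
# injectable trigger latencies, and synthetic EPID cine stacks, all with
# analytic ground truth so every analysis stage can be validated end-to-end.
#
# The simulator emulates a rigid reflector block on a mechanical motion
# phantom: strictly periodic motion on the AP axis, zero lateral motion. The
# default period of 5.32 s makes the planned 25%-75% window 2.66 s long.

#' Simulation configuration
#'
#' Parameters of one simulated gating session. The ground-truth phase is
#' analytic: phase(t) = (t mod period) / period, with the motion peak at
#' phase 0.
#'
#' @param period_s Respiratory period (default 5.32 s).
#' @param amplitude_cm Peak-to-trough motion amplitude (default 1 cm).
#' @param waveform `"sine"` (cosine with peak at t = 0; analytically
#'   tractable test default) or `"cos4"` (cos^4 shape with an end-exhale
#'   dwell, closer to real breathing).
#' @param n_cycles Number of simulated periods (default 6).
#' @param sample_rate_hz Log sampling rate (default 25 Hz).
#' @param noise_sd Gaussian amplitude noise SD in normalized units
#'   (fraction of `amplitude_cm`; default 0 -- a mechanical phantom trace is
#'   essentially noiseless).
#' @param gating_window Planned phase window (default `c(0.25, 0.75)`).
#' @param latency_on_s,latency_off_s Latency added to every beam-on /
#'   beam-off trigger edge (seconds; may be negative for early edges; |L|
#'   must stay below half a period).
#' @param epid_frame_period_s EPID cine frame period (default 0.04 s).
#' @param epid_noise_sd EPID pixel noise SD as a fraction of the beam-on
#'   signal amplitude (default 0).
#' @param epid_persistence_frames Number of exponentially decaying
#'   afterglow frames following beam-off (default 0).
#' @param epid_rows,epid_cols,epid_pixel_spacing_cm,epid_sid_cm,epid_sad_cm
#'   Imager geometry for simulated frames.
#' @param seed Integer RNG seed; required whenever any noise SD is > 0.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(period_s = 5.32, amplitude_cm = 1,
                       waveform = c("sine", "cos4"), n_cycles = 6,
                       sample_rate_hz = 25, noise_sd = 0,
                       gating_window = c(0.25, 0.75),
                       latency_on_s = 0, latency_off_s = 0,
                       epid_frame_period_s = 0.04, epid_noise_sd = 0,
                       epid_persistence_frames = 0,
                       epid_rows = 32, epid_cols = 32,
                       epid_pixel_spacing_cm = 0.3,
                       epid_sid_cm = 150, epid_sad_cm = 100,
                       seed = NULL) {
  waveform <- match.arg(waveform)
  check_number(period_s, "period_s", positive = TRUE)
  check_number(amplitude_cm, "amplitude_cm", positive = TRUE)
  check_number(n_cycles, "n_cycles", positive = TRUE)
  check_number(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  check_number(epid_frame_period_s, "epid_frame_period_s", positive = TRUE)
  if (length(gating_window) != 2L || gating_window[1] < 0 ||
      gating_window[2] > 1 || gating_window[1] >= gating_window[2]) {
    abort_gatelog("`gating_window` must satisfy 0 <= lo < hi <= 1.",
                  "gatelog_parameter_error")
  }
  if (max(abs(latency_on_s), abs(latency_off_s)) >= period_s / 2) {
    abort_gatelog("trigger latencies must be below half a period.",
                  "gatelog_parameter_error")
  }
  if ((noise_sd > 0 || epid_noise_sd > 0) && is.null(seed)) {
    abort_gatelog("`seed` is required when any noise SD is > 0.",
                  "gatelog_parameter_error")
  }
  structure(
    list(period_s = period_s, amplitude_cm = amplitude_cm,
         waveform = waveform, n_cycles = n_cycles,
         sample_rate_hz = sample_rate_hz, noise_sd = noise_sd,
         gating_window = gating_window,
         latency_on_s = latency_on_s, latency_off_s = latency_off_s,
         epid_frame_period_s = epid_frame_period_s,
         epid_noise_sd = epid_noise_sd,
         epid_persistence_frames = epid_persistence_frames,
         epid_rows = epid_rows, epid_cols = epid_cols,
         epid_pixel_spacing_cm = epid_pixel_spacing_cm,
         epid_sid_cm = epid_sid_cm, epid_sad_cm = epid_sad_cm,
         seed = seed),
    class = "sim_config"
  )
}

# Run fn with a locally-seeded RNG, restoring the caller's RNG state.
with_sim_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Simulate the phantom motion trace
#'
#' AP motion `z(t) = amplitude * w(2 pi t / period) + noise`, with `w`
#' either a cosine (peak at t = 0) or cos^4 (end-exhale dwell); x and y are
#' zero. Deterministic given the seed.
#'
#' @param cfg A [sim_config()].
#' @return A `motion_trace` tibble (`time_s`, `amp_x_cm`, `amp_y_cm`,
#'   `amp_z_cm`) with the nominal `sample_period` and the analytic truth
#'   (period, number of cycles) as attributes.
#' @export
simulate_motion <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  dt <- 1 / cfg$sample_rate_hz
  n <- round(cfg$n_cycles * cfg$period_s * cfg$sample_rate_hz)
  t <- (seq_len(n) - 1L) * dt
  w <- switch(cfg$waveform,
    sine = cos(2 * pi * t / cfg$period_s),
    cos4 = 2 * cos(pi * t / cfg$period_s)^4 - 1
  )
  z <- cfg$amplitude_cm * w
  if (cfg$noise_sd > 0) {
    z <- z + with_sim_seed(cfg$seed, function() {
      stats::rnorm(n, 0, cfg$noise_sd * cfg$amplitude_cm)
    })
  }
  out <- tibble(time_s = t, amp_x_cm = 0, amp_y_cm = 0, amp_z_cm = z)
  attr(out, "sample_period") <- dt
  attr(out, "truth") <- list(period_s = cfg$period_s, n_cycles = cfg$n_cycles,
                             peak_times = (0:(cfg$n_cycles - 1)) * cfg$period_s)
  class(out) <- c("motion_trace", class(out))
  out
}

# Analytic trigger-event table for a config: planned window edges per cycle
# and the actual (latency-shifted) edge times.
truth_events <- function(cfg) {
  k <- 0:(cfg$n_cycles - 1)
  T <- cfg$period_s
  tibble(
    cycle = k,
    t25_planned = (k + cfg$gating_window[1]) * T,
    t75_planned = (k + cfg$gating_window[2]) * T,
    t_on_true = (k + cfg$gating_window[1]) * T + cfg$latency_on_s,
    t_off_true = (k + cfg$gating_window[2]) * T + cfg$latency_off_s
  )
}

#' Simulate gated beam flags on the motion clock
#'
#' The ground-truth beam command is on while the analytic phase lies in
#' `[window lo, window hi)`; every rising edge is then delayed by
#' `latency_on_s` and every falling edge by `latency_off_s`, and the
#' resulting on/off event times are sampled onto the motion time base (a
#' sample is on iff it falls inside a shifted on-interval). Latencies are
#' applied to event times *before* resampling, so sub-sample latencies are
#' exercised. The true event table is retained as the `truth` attribute.
#'
#' @param motion A `motion_trace` from [simulate_motion()].
#' @param cfg The same [sim_config()].
#' @return A [gating_log()] combining the motion trace and the beam flags;
#'   attribute `truth` holds the analytic event table
#'   (`cycle`, `t25_planned`, `t75_planned`, `t_on_true`, `t_off_true`).
#' @export
simulate_gated_beam <- function(motion, cfg) {
  stopifnot(inherits(motion, "motion_trace"), inherits(cfg, "sim_config"))
  ev <- truth_events(cfg)
  t <- motion$time_s
  on <- rep(FALSE, length(t))
  for (i in seq_len(nrow(ev))) {
    on <- on | (t >= ev$t_on_true[i] & t < ev$t_off_true[i])
  }
  log <- gating_log(
    bind_cols(motion, tibble(beam_on = on)),
    session_id = sprintf("sim-%s", cfg$seed %||% "0"),
    metadata = c(
      source = "synthetic motion phantom",
      period_s = format(cfg$period_s),
      gating_window = paste(cfg$gating_window, collapse = "-"),
      latency_on_s = format(cfg$latency_on_s),
      latency_off_s = format(cfg$latency_off_s)
    ),
    sample_period = attr(motion, "sample_period")
  )
  attr(log, "truth") <- ev
  log
}

#' Simulate an EPID cine stack for a gated session
#'
#' Frames at `epid_frame_period_s`; while the (latency-shifted) beam is on,
#' the whole field is bright (the 10 x 10 cm field projects beyond the
#' simulated panel); background frames sit at a low dark-current level.
#' Optional afterglow adds exponentially decaying frames after each
#' beam-off, and Gaussian pixel noise is seeded through the config.
#'
#' @param log Gated log from [simulate_gated_beam()] (its `truth` attribute
#'   supplies the actual beam event times), or a `truth` event tibble.
#' @param cfg The [sim_config()].
#' @return An `epid_stack` covering the session span.
#' @export
simulate_epid_cine <- function(log, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ev <- if (is.data.frame(log) && all(c("t_on_true", "t_off_true") %in% names(log))) {
    log
  } else {
    attr(log, "truth") %||%
      abort_gatelog("`log` carries no truth events; pass the output of simulate_gated_beam().",
                    "gatelog_parameter_error")
  }
  fp <- cfg$epid_frame_period_s
  span <- cfg$n_cycles * cfg$period_s
  n_frames <- floor(span / fp)
  times <- (seq_len(n_frames) - 1L) * fp
  bg <- 5; hi <- 1000
  level <- rep(bg, n_frames)
  on_mask <- rep(FALSE, n_frames)
  for (i in seq_len(nrow(ev))) {
    on_mask <- on_mask | (times >= ev$t_on_true[i] & times < ev$t_off_true[i])
  }
  level[on_mask] <- hi
  if (cfg$epid_persistence_frames > 0) {
    falls <- which(diff(c(FALSE, on_mask)) == -1)
    for (f in falls) {
      for (j in seq_len(cfg$epid_persistence_frames)) {
        k <- f + j - 1L
        if (k <= n_frames && !on_mask[k]) {
          level[k] <- max(level[k], bg + (hi - bg) * 0.6 * exp(-(j - 1)))
        }
      }
    }
  }
  frames <- array(rep(level, each = cfg$epid_rows * cfg$epid_cols),
                  dim = c(cfg$epid_rows, cfg$epid_cols, n_frames))
  if (cfg$epid_noise_sd > 0) {
    noise <- with_sim_seed(cfg$seed + 1L, function() {
      stats::rnorm(length(frames), 0, cfg$epid_noise_sd * (hi - bg))
    })
    frames <- frames + array(noise, dim = dim(frames))
  }
  new_epid_stack(frames, times, fp, cfg$epid_pixel_spacing_cm,
                 cfg$epid_sid_cm, cfg$epid_sad_cm)
}

#' Write a complete synthetic fixture set
#'
#' Generates one session (motion + gated beam + EPID stack) and writes the
#' gating-log CSV, the EPID stack directory, and a ground-truth JSON
#' (planned phase times, actual trigger events, injected latencies) intended
#' only for validation against the pipeline's estimates.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if absent).
#' @return Tibble manifest: `file`, `role`.
#' @export
make_fixture_set <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  motion <- simulate_motion(cfg)
  log <- simulate_gated_beam(motion, cfg)
  log_path <- file.path(out_dir, "gating_log.csv")
  write_gating_log(log, log_path)
  epid_dir <- file.path(out_dir, "epid")
  write_epid_stack(simulate_epid_cine(log, cfg), epid_dir)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(period_s = cfg$period_s, n_cycles = cfg$n_cycles,
         gating_window = cfg$gating_window,
         latency_on_s = cfg$latency_on_s, latency_off_s = cfg$latency_off_s,
         events = attr(log, "truth")),
    truth_path, auto_unbox = TRUE, digits = NA
  )
  tibble(
    file = c(log_path, file.path(epid_dir, "sidecar.json"),
             file.path(epid_dir, "frames.csv"), truth_path),
    role = c("gating_log", "epid_sidecar", "epid_frames", "ground_truth")
  )
}
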