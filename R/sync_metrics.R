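# Pairing of respiratory cycles with beam intervals, per-cycle timing deltas,
# aggregate statistics, dose comparison and multi-session trending.
#
# Sign convention throughout: delta = trigger time minus planned phase time,
# so a positive delta means the trigger fired *after* the planned phase point.
# Per record, delta_on - delta_off == trigger_duration - window_duration is an
# algebraic identity.

#' Aggregate statistics (mean, SD, median, n)
#'
#' The summary used in every QA table: arithmetic mean, standard deviation
#' and median. The SD is the *population* SD (divisor n) by default -- the
#' convention of gating QA summary tables, where the 5-6 cycles of a session
#' are the complete population of delivered cycles, not a sample. The median
#' of an even count is the midpoint of the two central order statistics.
#' All internal math is full precision; rounding (2 decimals, half away from
#' zero) is applied only at the reporting layer ([render_report()],
#' [round_half_up()]).
#'
#' @param x Numeric vector (seconds or cGy); must be non-empty and finite
#'   (exclude missing entries before the call).
#' @param sd_type `"population"` (divisor n, default) or `"sample"`
#'   (divisor n - 1).
#' @return One-row tibble: `mean`, `sd`, `median`, `n`.
#' @export
#' @examples
#' aggregate_stats(c(-0.01, 0.10, 0.04, 0.01, -0.02))
aggregate_stats <- function(x, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(x) == 0L) {
    abort_gatelog("cannot aggregate an empty vector.",
                  "gatelog_empty_input_error")
  }
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort_gatelog("values must be finite numbers (drop N/A entries first).",
                  "gatelog_parameter_error")
  }
  s <- if (sd_type == "population") pop_sd(x) else stats::sd(x)
  if (length(x) == 1L) s <- 0
  tibble(mean = mean(x), sd = s, median = stats::median(x), n = length(x))
}

#' Pair respiratory cycles with beam intervals
#'
#' Assigns each complete beam interval to the cycle whose planned gating
#' window (\[t25, t75\] by default) it overlaps most, one-to-one, greedily by
#' overlap with ties resolved toward the earlier cycle. Unmatched cycles and
#' intervals are reported in attributes, never silently dropped.
#'
#' @param cycles Cycle table from [segment_cycles()].
#' @param intervals Interval table from [detect_beam_intervals()]; only
#'   complete intervals are paired.
#' @param window Planned gating window as phase fractions (default
#'   `c(0.25, 0.75)`).
#' @return Tibble of per-cycle synchronization records: `cycle_index`, `t25`,
#'   `t75`, `t_on`, `t_off`, `delta_on` (= t_on - t25), `delta_off`
#'   (= t_off - t75), `window_duration`, `trigger_duration`; attributes
#'   `unmatched_cycles` and `unmatched_intervals`.
#' @export
pair_cycles_intervals <- function(cycles, intervals, window = c(0.25, 0.75)) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  ints <- dplyr::filter(intervals, .data$complete)
  if (nrow(cycles) < 1L || nrow(ints) < 1L) {
    abort_gatelog("need at least one cycle and one complete beam interval.",
                  "gatelog_pairing_error")
  }
  ph <- phase_time(cycles, window) %>%
    tidyr::pivot_wider(names_from = "fraction", values_from = "time") %>%
    stats::setNames(c("cycle_index", "t25", "t75"))
  cand <- tidyr::crossing(
    ph,
    tibble(interval = seq_len(nrow(ints)),
           t_on = ints$t_on, t_off = ints$t_off)
  ) %>%
    mutate(overlap = pmax(0, pmin(.data$t_off, .data$t75) -
                             pmax(.data$t_on, .data$t25))) %>%
    filter(.data$overlap > 0) %>%
    arrange(dplyr::desc(.data$overlap), .data$cycle_index, .data$interval)

  used_c <- integer(); used_i <- integer(); keep <- integer()
  for (k in seq_len(nrow(cand))) {
    if (!(cand$cycle_index[k] %in% used_c) && !(cand$interval[k] %in% used_i)) {
      keep <- c(keep, k)
      used_c <- c(used_c, cand$cycle_index[k])
      used_i <- c(used_i, cand$interval[k])
    }
  }
  if (length(keep) == 0L) {
    abort_gatelog(
      sprintf("no beam interval overlaps any planned gating window (%d cycles, %d intervals).",
              nrow(cycles), nrow(ints)),
      "gatelog_pairing_error"
    )
  }
  out <- cand[keep, ] %>%
    mutate(
      delta_on = .data$t_on - .data$t25,
      delta_off = .data$t_off - .data$t75,
      window_duration = .data$t75 - .data$t25,
      trigger_duration = .data$t_off - .data$t_on
    ) %>%
    select("cycle_index", "t25", "t75", "t_on", "t_off",
           "delta_on", "delta_off", "window_duration", "trigger_duration") %>%
    arrange(.data$cycle_index)
  attr(out, "unmatched_cycles") <- setdiff(cycles$index, used_c)
  attr(out, "unmatched_intervals") <- setdiff(seq_len(nrow(ints)), used_i)
  out
}

#' Bundle per-cycle records into a session result
#'
#' @param records Per-cycle record table from [pair_cycles_intervals()].
#' @param session_id Session identifier.
#' @param sd_type SD convention passed to [aggregate_stats()].
#' @return A `qa_session` object: per-cycle records, aggregates of
#'   `delta_on`, `delta_off`, `window_duration` and `trigger_duration`, and
#'   `duration_gap` (mean window duration minus mean trigger duration).
#' @export
session_result <- function(records, session_id = "session",
                           sd_type = "population") {
  if (nrow(records) < 1L) {
    abort_gatelog("a session needs at least one paired record.",
                  "gatelog_empty_input_error")
  }
  metrics <- c("delta_on", "delta_off", "window_duration", "trigger_duration")
  aggregates <- purrr::map_dfr(metrics, function(m) {
    bind_cols(tibble(metric = m), aggregate_stats(records[[m]], sd_type))
  })
  structure(
    list(
      session_id = session_id,
      records = records,
      aggregates = aggregates,
      duration_gap = mean(records$window_duration) -
        mean(records$trigger_duration),
      sd_type = sd_type
    ),
    class = "qa_session"
  )
}

#' Full log-to-session analysis pipeline
#'
#' Runs the whole temporal-synchronization chain on one gating log: extract
#' the AP component, min-max normalize, moving-mean smooth, segment cycles,
#' compute window phase times, detect beam intervals, pair and aggregate.
#'
#' @param log A [gating_log()].
#' @param axis Motion axis carrying the respiratory surrogate (default "z").
#' @param smooth_window Moving-mean window in samples (default 5).
#' @param min_prominence,min_separation_fraction Peak-detection parameters,
#'   see [segment_cycles()].
#' @param window Planned gating window fractions (default `c(0.25, 0.75)`).
#' @param strict_edges Passed to [detect_beam_intervals()].
#' @param sd_type SD convention (default population).
#' @return A `qa_session` object (see [session_result()]); the conditioned
#'   signal and cycle table are attached as `$signal` and `$cycles`.
#' @export
analyze_gating_session <- function(log, axis = "z", smooth_window = 5,
                                   min_prominence = 0.2,
                                   min_separation_fraction = 0.4,
                                   window = c(0.25, 0.75),
                                   strict_edges = FALSE,
                                   sd_type = "population") {
  sig <- extract_component(log, axis) %>%
    minmax_normalize() %>%
    moving_mean_smooth(smooth_window)
  cycles <- segment_cycles(sig, min_prominence, min_separation_fraction)
  if (nrow(cycles) == 0L) {
    abort_gatelog(
      paste0("no respiratory cycles detected: ", attr(cycles, "diagnostic")),
      "gatelog_pairing_error"
    )
  }
  intervals <- detect_beam_intervals(log, strict_edges = strict_edges)
  records <- pair_cycles_intervals(cycles, intervals, window)
  res <- session_result(records, attr(log, "session_id"), sd_type)
  res$signal <- sig
  res$cycles <- cycles
  res$intervals <- intervals
  res
}

#' Compare planned window duration with trigger-on duration
#'
#' Per-cycle gap = window_duration - trigger_duration; a systematic positive
#' gap means the beam is on for less time than the planned 25%-75% window
#' (late beam-on and/or early beam-off).
#'
#' @param session A `qa_session`.
#' @return One-row tibble with aggregates of the per-cycle gap (`mean` is
#'   the session `duration_gap`).
#' @export
duration_comparison <- function(session) {
  stopifnot(inherits(session, "qa_session"))
  gaps <- session$records$window_duration - session$records$trigger_duration
  aggregate_stats(gaps, session$sd_type)
}

#' Compare gated and non-gated ion-chamber doses
#'
#' Output-constancy check: point doses measured with gating are compared
#' against the non-gated reference delivery. In paired mode the per-pair
#' differences (gated - reference, paired by measurement index) are
#' summarised alongside the two arms; in unpaired mode only the arm
#' aggregates are reported.
#'
#' @param reference Non-gated reference doses (cGy), all > 0.
#' @param gated Gated-delivery doses (cGy), all > 0.
#' @param paired Pair measurements by index (requires equal lengths).
#' @param sd_type SD convention (default population).
#' @return Tibble with one row per arm (`reference`, `gated`, and
#'   `difference` when paired): `arm`, `mean`, `sd`, `median`, `n`;
#'   attribute `paired_diffs` carries the difference vector in paired mode.
#' @export
dose_comparison <- function(reference, gated, paired = TRUE,
                            sd_type = "population") {
  if (any(reference <= 0) || any(gated <= 0)) {
    abort_gatelog("doses must be positive (cGy).", "gatelog_parameter_error")
  }
  if (paired && length(reference) != length(gated)) {
    abort_gatelog("paired dose comparison requires equal-length lists.",
                  "gatelog_parameter_error")
  }
  arms <- list(reference = reference, gated = gated)
  if (paired) arms$difference <- gated - reference
  out <- purrr::imap_dfr(arms, function(v, nm) {
    bind_cols(tibble(arm = nm), aggregate_stats(v, sd_type))
  })
  if (paired) attr(out, "paired_diffs") <- gated - reference
  out
}

#' Multi-session reproducibility trend
#'
#' Tabulates each session's aggregates (trigger duration, window duration,
#' delta_on, delta_off) in session order and reports the maximum absolute
#' drift of each metric's mean across sessions -- the month-to-month
#' constancy figure of a periodic QA programme.
#'
#' @param sessions List of `qa_session` objects, in chronological order.
#' @return A `qa_trend` object: `$per_session` (long tibble: `session_id`,
#'   `metric`, `mean`, `sd`, `median`, `n`) and `$drift` (`metric`,
#'   `max_abs_drift` = max |mean_i - mean_j| over session pairs).
#' @export
reproducibility_trend <- function(sessions) {
  if (length(sessions) < 1L) {
    abort_gatelog("at least one session is required.",
                  "gatelog_empty_input_error")
  }
  per_session <- purrr::map_dfr(sessions, function(s) {
    bind_cols(tibble(session_id = s$session_id), s$aggregates)
  })
  per_session$session_id <- factor(per_session$session_id,
                                   levels = unique(per_session$session_id))
  drift <- per_session %>%
    group_by(.data$metric) %>%
    summarise(max_abs_drift = max(.data$mean) - min(.data$mean),
              .groups = "drop")
  structure(list(per_session = per_session, drift = drift),
            class = "qa_trend")
}

#' @export
print.qa_session <- function(x, ...) {
  cat(sprintf("<qa_session> \"%s\": %d paired cycles, duration gap %.3f s\n",
              x$session_id, nrow(x$records), x$duration_gap))
  print(x$aggregates)
  invisible(x)
}

#' @export
print.qa_trend <- function(x, ...) {
  cat(sprintf("<qa_trend> %d sessions\n",
              length(unique(x$per_session$session_id))))
  print(x$drift)
  invisible(x)
}
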