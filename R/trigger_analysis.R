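# Beam-on interval extraction from the trigger flag sequence.

#' Detect beam-on intervals from the trigger flags
#'
#' Scans the beam flag for state transitions. A rising edge is stamped at the
#' first sample in the on state (0 -> 1), a falling edge at the first sample
#' back off (1 -> 0); edge times are sample timestamps, giving a
#' resolution-bounded bias below one sample period. A trace that ends while
#' the beam is on yields a final interval with `complete = FALSE` (excluded
#' from duration statistics). A trace that *starts* on has an unseen leading
#' edge: by default the interval is kept complete with
#' `leading_edge_seen = FALSE` and a warning; `strict_edges = TRUE` demotes
#' it to incomplete.
#'
#' @param beam A [gating_log()], or any data frame with `time_s` and
#'   `beam_on` columns, or with `t` and `on` columns.
#' @param strict_edges If `TRUE`, an interval whose rising edge precedes the
#'   trace is marked incomplete rather than merely flagged.
#' @return Tibble of intervals: `t_on`, `t_off`, `duration` (seconds),
#'   `complete`, `leading_edge_seen`, ordered in time. An all-off trace
#'   yields zero rows.
#' @export
detect_beam_intervals <- function(beam, strict_edges = FALSE) {
  if (all(c("time_s", "beam_on") %in% names(beam))) {
    t <- beam$time_s; on <- as.logical(beam$beam_on)
  } else if (all(c("t", "on") %in% names(beam))) {
    t <- beam$t; on <- as.logical(beam$on)
  } else {
    abort_gatelog("`beam` needs columns time_s/beam_on (or t/on).",
                  "gatelog_parameter_error")
  }
  if (any(diff(t) <= 0)) {
    abort_gatelog("trigger time axis must be strictly increasing.",
                  "gatelog_validation_error")
  }
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on_runs <- which(r$values)
  if (length(on_runs) == 0L) {
    return(tibble(t_on = double(), t_off = double(), duration = double(),
                  complete = logical(), leading_edge_seen = logical()))
  }
  n <- length(on)
  out <- tibble(
    t_on = t[starts[on_runs]],
    t_off = ifelse(ends[on_runs] < n, t[ends[on_runs] + 1L], NA_real_),
    leading_edge_seen = starts[on_runs] > 1L
  ) %>%
    mutate(
      complete = !is.na(t_off) & (.data$leading_edge_seen | !strict_edges),
      duration = .data$t_off - .data$t_on
    ) %>%
    select("t_on", "t_off", "duration", "complete", "leading_edge_seen")
  if (any(!out$leading_edge_seen)) {
    rlang::warn("trace starts with beam on: leading rising edge not observed.",
                class = "gatelog_leading_edge_unseen")
  }
  out
}

#' Aggregate statistics of beam-on durations
#'
#' Mean, population SD, median and count over *complete* intervals only.
#'
#' @param intervals Interval table from [detect_beam_intervals()].
#' @return One-row [aggregate_stats()] tibble.
#' @export
interval_duration_stats <- function(intervals) {
  d <- intervals$duration[intervals$complete]
  if (length(d) == 0L) {
    abort_gatelog("no complete beam intervals to summarise.",
                  "gatelog_empty_input_error")
  }
  aggregate_stats(d)
}
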