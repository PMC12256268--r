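# Conditioning and cycle segmentation of the respiratory surrogate signal.
#
# The analysis chain mirrors standard phase-gating practice: extract the
# anterior-posterior component, min-max normalize, smooth with a centred
# five-sample moving mean, anchor cycles peak-to-peak (0% phase = end-inhale
# peak) and treat phase as linear in time within each cycle, so the 25%-75%
# planned window is the end-exhale half cycle.

#' Extract one motion axis as a 1-D signal
#'
#' @param motion A [gating_log()] or any data frame with a `time_s` column
#'   and `amp_x_cm`/`amp_y_cm`/`amp_z_cm` columns.
#' @param axis One of `"x"`, `"y"`, `"z"` (z = anterior-posterior, the
#'   gating surrogate axis; default).
#' @return A tibble with columns `t` (seconds) and `v` (cm), on the original
#'   time base with untouched values.
#' @export
extract_component <- function(motion, axis = c("z", "x", "y")) {
  if (is.character(axis) && length(axis) == 1L && !axis %in% c("x", "y", "z")) {
    abort_gatelog(sprintf("unknown axis \"%s\"; use \"x\", \"y\" or \"z\".", axis),
                  "gatelog_parameter_error")
  }
  axis <- match.arg(axis)
  col <- paste0("amp_", axis, "_cm")
  tibble(t = motion$time_s, v = motion[[col]])
}

#' Min-max normalize a signal
#'
#' Rescales `v` to `(v - min v) / (max v - min v)`, so the output lies in
#' \[0, 1\] and attains both endpoints. A constant signal has no amplitude to
#' normalize; it is returned as all zeros with a `degenerate` attribute and a
#' warning, so downstream segmentation can refuse it cleanly.
#'
#' @param signal Tibble with columns `t` and `v` (at least 2 samples).
#' @return Tibble with `v` rescaled; attribute `degenerate` is `TRUE` for
#'   constant input.
#' @export
minmax_normalize <- function(signal) {
  v <- signal$v
  if (length(v) < 2L) {
    abort_gatelog("normalization needs at least 2 samples.",
                  "gatelog_parameter_error")
  }
  rng <- range(v)
  if (diff(rng) == 0) {
    rlang::warn("constant signal: min-max normalization is degenerate, returning zeros.",
                class = "gatelog_degenerate_signal")
    out <- tibble(t = signal$t, v = rep(0, length(v)))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- tibble(t = signal$t, v = (v - rng[1]) / (rng[2] - rng[1]))
  attr(out, "degenerate") <- FALSE
  out
}

#' Centred moving-mean smoothing
#'
#' Centred moving average with an odd window, the endpoint windows shrinking
#' to the available samples (the first/last outputs average fewer points
#' rather than padding), so output length equals input length. Window 1 is
#' the identity.
#'
#' @param signal Tibble with columns `t` and `v`.
#' @param window Odd positive integer window length in samples (default 5).
#' @return Tibble with smoothed `v`.
#' @export
moving_mean_smooth <- function(signal, window = 5) {
  n <- nrow(signal)
  if (!is.numeric(window) || length(window) != 1L || window < 1 ||
      window != as.integer(window) || window %% 2 == 0) {
    abort_gatelog("`window` must be an odd positive integer.",
                  "gatelog_parameter_error")
  }
  if (window > n) {
    abort_gatelog("`window` must not exceed the signal length.",
                  "gatelog_parameter_error")
  }
  h <- (window - 1L) / 2L
  # cumulative-sum evaluation of the truncated centred mean
  cs <- c(0, cumsum(signal$v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  tibble(t = signal$t, v = (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

# Topographic prominence of a local maximum at index i: height above the
# higher of the two "key cols", each the minimum between the peak and the
# nearest strictly higher sample on that side (or over the whole side if no
# higher sample exists). Boundary peaks use the interior side only.
peak_prominence <- function(v, i) {
  h <- v[i]
  side_col <- function(idx) {
    if (length(idx) == 0L) return(NA_real_)
    m <- Inf
    for (j in idx) {
      if (v[j] > h) break
      if (v[j] < m) m <- v[j]
    }
    if (is.infinite(m)) NA_real_ else m
  }
  colL <- side_col(rev(seq_len(i - 1L)))
  colR <- side_col(seq(i + 1L, length(v), length.out = max(0L, length(v) - i)))
  ref <- suppressWarnings(max(colL, colR, na.rm = TRUE))
  if (is.infinite(ref)) 0 else h - ref
}

# Local-maximum candidates. A peak must be confirmed by an observed
# non-increase after it: the first sample qualifies when the signal descends
# from it (a trace starting exactly on a peak anchors the first cycle), but
# the last sample never does -- a trailing rise is a truncated ascent toward
# an unobserved peak, and the partial cycle it would close is discarded.
peak_candidates <- function(v) {
  n <- length(v)
  if (n < 2L) return(integer())
  cand <- integer()
  if (v[1] > v[2]) cand <- c(cand, 1L)
  if (n >= 3L) {
    i <- 2:(n - 1L)
    cand <- c(cand, i[v[i] > v[i - 1L] & v[i] >= v[i + 1L]])
  }
  sort(cand)
}

# Coarse period estimate (in samples) from the autocorrelation maximum after
# its first local minimum; NA when no periodic structure is found.
estimate_period_samples <- function(v) {
  n <- length(v)
  a <- stats::acf(v, lag.max = n - 1L, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  if (anyNA(a)) return(NA_real_)
  r <- a[-1]                                   # lags 1 .. n-1
  dips <- which(diff(r) > 0)                   # first rise after the initial decay
  if (length(dips) == 0L) return(NA_real_)
  from <- dips[1] + 1L
  which.max(r[from:length(r)]) + from - 1L
}

#' Segment a respiratory signal into cycles
#'
#' Detects signal peaks and anchors one respiratory cycle between each pair
#' of successive peaks (peak = 0% phase). A coarse period estimate from the
#' autocorrelation maximum sets the minimum peak separation
#' (`min_separation_fraction` x estimate); candidate peaks must exceed
#' `min_prominence` (topographic prominence, in the normalized units of the
#' input). Partial leading/trailing cycles -- samples before the first or
#' after the last detected peak -- are discarded, not extrapolated.
#'
#' The input is expected normalized ([minmax_normalize()]) and smoothed
#' ([moving_mean_smooth()]) and should span at least two periods. Fewer than
#' two detected peaks yields an empty cycle table carrying a `diagnostic`
#' attribute rather than an error.
#'
#' @param signal Tibble with columns `t`, `v`.
#' @param min_prominence Minimum peak prominence in normalized units
#'   (default 0.2).
#' @param min_separation_fraction Minimum peak separation as a fraction of
#'   the autocorrelation period estimate (default 0.4).
#' @param anchor `"peak"` (default) anchors cycles at signal maxima
#'   (end-inhale); `"trough"` at minima.
#' @return Tibble of cycles: `index` (0-based), `t_start`, `t_end`, `period`
#'   (seconds), ordered and non-overlapping; attribute `peaks` holds the
#'   anchor sample indices.
#' @export
segment_cycles <- function(signal, min_prominence = 0.2,
                           min_separation_fraction = 0.4,
                           anchor = c("peak", "trough")) {
  anchor <- match.arg(anchor)
  v <- if (anchor == "trough") -signal$v else signal$v
  t <- signal$t
  empty <- function(msg) {
    out <- tibble(index = integer(), t_start = double(),
                  t_end = double(), period = double())
    attr(out, "diagnostic") <- msg
    attr(out, "peaks") <- integer()
    out
  }
  cand <- peak_candidates(v)
  if (length(cand) == 0L) {
    return(empty("no local maxima found (flat or monotone signal)."))
  }
  prom <- vapply(cand, function(i) peak_prominence(v, i), numeric(1))
  cand <- cand[prom >= min_prominence]
  if (length(cand) < 2L) {
    return(empty(sprintf("fewer than 2 peaks exceed prominence %.3f.",
                         min_prominence)))
  }
  per <- estimate_period_samples(v)
  min_sep <- if (is.na(per)) 1 else min_separation_fraction * per
  # greedy by height, ties to the earlier sample
  ord <- cand[order(-v[cand], cand)]
  kept <- integer()
  for (i in ord) {
    if (all(abs(i - kept) >= min_sep)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  if (length(kept) < 2L) {
    return(empty("fewer than 2 peaks after separation filtering."))
  }
  out <- tibble(
    index = seq_len(length(kept) - 1L) - 1L,
    t_start = t[kept[-length(kept)]],
    t_end = t[kept[-1]]
  ) %>% mutate(period = t_end - t_start)
  attr(out, "peaks") <- kept
  out
}

#' Phase-crossing times within cycles
#'
#' Phase is linear in time within a cycle: the `fraction` phase point of a
#' cycle occurs at `t_start + fraction * period`. Fraction 0 is the anchoring
#' peak, 0.25 and 0.75 are the planned gating-window edges, 1 the next peak.
#'
#' @param cycles Cycle table from [segment_cycles()] (or any tibble with
#'   `index`, `t_start`, `period`).
#' @param fraction One or more phase fractions in \[0, 1\].
#' @return Tibble with columns `cycle_index`, `fraction`, `time` (seconds),
#'   one row per cycle x fraction.
#' @export
phase_time <- function(cycles, fraction) {
  if (!is.numeric(fraction) || any(fraction < 0 | fraction > 1)) {
    abort_gatelog("`fraction` must lie in [0, 1].", "gatelog_parameter_error")
  }
  tidyr::crossing(
    tibble(cycle_index = cycles$index, t_start = cycles$t_start,
           period = cycles$period),
    tibble(fraction = fraction)
  ) %>%
    mutate(time = t_start + fraction * period) %>%
    select("cycle_index", "fraction", "time") %>%
    arrange(.data$cycle_index, .data$fraction)
}

#' Average periodic signal across cycles
#'
#' Maps each cycle's samples to phase fractions, interpolates them linearly
#' onto a common uniform phase grid, and accumulates the per-grid-point mean
#' and population SD across cycles -- the "average breath" display used to
#' visualise gating-window placement.
#'
#' @param signal Tibble with columns `t`, `v` (the signal the cycles were
#'   segmented from).
#' @param cycles Cycle table from [segment_cycles()]; at least 1 cycle.
#' @param grid_points Number of uniform phase-grid points over \[0, 1\]
#'   (default 101).
#' @return An `avg_periodic_signal` tibble: `phase`, `mean_v`, `sd_v`
#'   (population SD), with attribute `n_cycles`.
#' @export
average_periodic_signal <- function(signal, cycles, grid_points = 101) {
  if (nrow(cycles) < 1L) {
    abort_gatelog("at least one cycle is required.", "gatelog_parameter_error")
  }
  check_number(grid_points, "grid_points", positive = TRUE)
  grid <- seq(0, 1, length.out = grid_points)
  per_cycle <- vapply(seq_len(nrow(cycles)), function(i) {
    tq <- cycles$t_start[i] + grid * cycles$period[i]
    stats::approx(signal$t, signal$v, xout = tq, rule = 2)$y
  }, numeric(grid_points))
  per_cycle <- matrix(per_cycle, nrow = grid_points)
  out <- tibble(
    phase = grid,
    mean_v = rowMeans(per_cycle),
    sd_v = apply(per_cycle, 1, pop_sd)
  )
  attr(out, "n_cycles") <- nrow(cycles)
  class(out) <- c("avg_periodic_signal", class(out))
  out
}
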