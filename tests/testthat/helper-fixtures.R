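# Shared fixtures and independent brute-force oracles.

# Write a minimal well-formed gating log file; returns the path.
write_minimal_log <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

minimal_log_lines <- c(
  "time_s,amp_x_cm,amp_y_cm,amp_z_cm,beam_on",
  "0.00,0,0,0,0",
  "0.04,0,0,1,1",
  "0.08,0,0,0,0"
)

# A cosine test signal tibble sampled at `rate` Hz for `n_periods` periods.
cosine_signal <- function(period = 4, rate = 25, n_periods = 6,
                          noise_sd = 0, seed = NULL) {
  n <- round(n_periods * period * rate)
  t <- (seq_len(n) - 1) / rate
  v <- cos(2 * pi * t / period)
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v + rnorm(n, 0, noise_sd)
  }
  tibble::tibble(t = t, v = v)
}

# Brute-force moving mean with truncated centred windows.
oracle_movmean <- function(v, window) {
  h <- (window - 1) / 2
  n <- length(v)
  vapply(seq_len(n), function(i) {
    mean(v[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

# Brute-force run-length scan of a boolean flag sequence: complete on-runs
# as (first-on-time, first-off-time).
oracle_intervals <- function(t, on) {
  out <- NULL
  i <- 1
  n <- length(on)
  while (i <= n) {
    if (on[i]) {
      j <- i
      while (j <= n && on[j]) j <- j + 1
      if (j <= n) out <- rbind(out, c(t[i], t[j]))
      i <- j
    } else {
      i <- i + 1
    }
  }
  out
}

# Brute-force aggregate formulas (population SD).
oracle_stats <- function(x) {
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / length(x))
  xs <- sort(x)
  n <- length(x)
  med <- if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
  c(mean = m, sd = s, median = med)
}

# Exhaustive local-maximum scan with the same prominence rule as
# segment_cycles: every interior strict-rise/non-increase local max plus a
# descending first sample, prominence above threshold.
oracle_peaks <- function(v, min_prominence) {
  n <- length(v)
  cand <- integer()
  if (v[1] > v[2]) cand <- c(cand, 1L)
  for (i in 2:(n - 1)) {
    if (v[i] > v[i - 1] && v[i] >= v[i + 1]) cand <- c(cand, i)
  }
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    h <- v[i]
    colL <- colR <- NA_real_
    if (i > 1) {
      m <- Inf
      for (j in (i - 1):1) {
        if (v[j] > h) break
        m <- min(m, v[j])
      }
      if (is.finite(m)) colL <- m
    }
    if (i < n) {
      m <- Inf
      for (j in (i + 1):n) {
        if (v[j] > h) break
        m <- min(m, v[j])
      }
      if (is.finite(m)) colR <- m
    }
    ref <- suppressWarnings(max(colL, colR, na.rm = TRUE))
    prom <- if (is.infinite(ref)) 0 else h - ref
    keep[k] <- prom >= min_prominence
  }
  cand[keep]
}

# One fully-simulated session (log + truth) for given latencies and seed.
sim_session <- function(latency_on = 0, latency_off = 0, seed = 1,
                        n_cycles = 6, period = 5.32, noise_sd = 0, ...) {
  cfg <- sim_config(period_s = period, n_cycles = n_cycles,
                    latency_on_s = latency_on, latency_off_s = latency_off,
                    noise_sd = noise_sd, seed = seed, ...)
  simulate_gated_beam(simulate_motion(cfg), cfg)
}
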