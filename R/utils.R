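# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Reporting-layer rounding used for all printed seconds and cGy values.
#' Base `round()` rounds half to even; QA summary tables conventionally round
#' half away from zero (0.045 -> 0.05, -0.045 -> -0.05).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.045, -0.045, 0.044), 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Population standard deviation (divisor n).
pop_sd <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

# Stop with a classed condition so tests can target error classes.
abort_gatelog <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "gatelog_error"), ...)
}

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    abort_gatelog(sprintf("`%s` must be a single finite number.", name),
                  "gatelog_parameter_error")
  }
  if (positive && x <= 0) {
    abort_gatelog(sprintf("`%s` must be > 0.", name), "gatelog_parameter_error")
  }
  invisible(x)
}

# Infer the nominal sample period as the median of successive differences.
infer_sample_period <- function(t) {
  stats::median(diff(t))
}

# Validate near-uniform sampling: every gap within tol_frac of the nominal period.
check_uniform_sampling <- function(t, sample_period, tol_frac = 0.1,
                                   what = "trace") {
  gaps <- diff(t)
  bad <- which(abs(gaps - sample_period) > tol_frac * sample_period)
  if (length(bad) > 0L) {
    abort_gatelog(
      sprintf(
        "%s sampling is non-uniform: gap %d (%.6f s) deviates from the nominal period %.6f s by more than %.0f%%.",
        what, bad[1], gaps[bad[1]], sample_period, 100 * tol_frac
      ),
      "gatelog_validation_error"
    )
  }
  invisible(TRUE)
}
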