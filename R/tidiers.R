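# broom-style tidiers for fitted/derived objects.

#' Tidy a QA session into per-cycle records
#'
#' @param x A `qa_session`.
#' @param ... Ignored.
#' @return The per-cycle record tibble with a `session_id` column prepended.
#' @export
tidy.qa_session <- function(x, ...) {
  bind_cols(tibble(session_id = x$session_id), x$records)
}

#' One-row summary of a QA session
#'
#' @param x A `qa_session`.
#' @param ... Ignored.
#' @return One-row tibble: per-metric means and SDs (`delta_on_mean`,
#'   `delta_on_sd`, ...), `duration_gap`, and `n_cycles`.
#' @export
glance.qa_session <- function(x, ...) {
  wide <- x$aggregates %>%
    select("metric", "mean", "sd") %>%
    tidyr::pivot_wider(names_from = "metric", values_from = c("mean", "sd"),
                       names_glue = "{metric}_{.value}")
  bind_cols(tibble(session_id = x$session_id), wide,
            tibble(duration_gap = x$duration_gap,
                   n_cycles = nrow(x$records)))
}

#' Tidy a QA report into its tolerance checks
#'
#' @param x A `qa_report`.
#' @param ... Ignored.
#' @return The checks tibble (`metric`, `value`, `tolerance`, `status`).
#' @export
tidy.qa_report <- function(x, ...) x$checks

#' One-row summary of a QA report
#'
#' @param x A `qa_report`.
#' @param ... Ignored.
#' @return One-row tibble: session id, cycle count, duration gap, number of
#'   passed/failed checks and overall `pass`.
#' @export
glance.qa_report <- function(x, ...) {
  tibble(
    session_id = x$session$session_id,
    n_cycles = nrow(x$session$records),
    duration_gap = x$session$duration_gap,
    n_pass = sum(x$checks$status == "pass"),
    n_fail = sum(x$checks$status == "fail"),
    pass = all(x$checks$status != "fail")
  )
}

#' Tidy a reproducibility trend
#'
#' @param x A `qa_trend`.
#' @param ... Ignored.
#' @return The long per-session aggregate tibble.
#' @export
tidy.qa_trend <- function(x, ...) x$per_session

#' One-row drift summary of a reproducibility trend
#'
#' @param x A `qa_trend`.
#' @param ... Ignored.
#' @return One-row tibble of per-metric maximum absolute mean drift.
#' @export
glance.qa_trend <- function(x, ...) {
  tidyr::pivot_wider(x$drift, names_from = "metric",
                     values_from = "max_abs_drift",
                     names_glue = "{metric}_drift")
}
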