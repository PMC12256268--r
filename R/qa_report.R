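# Session-level QA orchestration: tolerance policy, report assembly,
# rendering to JSON/CSV, and provenance.

#' Tolerance policy for gating QA
#'
#' Action thresholds for the temporal and dosimetric checks. The 0.10 s
#' timing default follows the TG-142-style 100 ms gating temporal-accuracy
#' tolerance; the dose default is 0.5% of the reference-arm mean, the usual
#' output-constancy acceptability bound. Boundary equality passes. Each
#' metric can be disabled, in which case it is reported as "not evaluated"
#' rather than pass/fail.
#'
#' @param max_abs_mean_delta_s Tolerance on |mean delta_on| and
#'   |mean delta_off| (seconds, default 0.10).
#' @param max_abs_duration_gap_s Tolerance on |mean window - mean trigger
#'   duration| (seconds, default 0.10).
#' @param max_dose_diff_pct Tolerance on |mean paired dose difference| as a
#'   percentage of the reference mean (default 0.5).
#' @param enabled Named logical vector switching individual metrics
#'   (`delta_on`, `delta_off`, `duration_gap`, `dose`).
#' @return A `tolerance_policy` list.
#' @export
tolerance_policy <- function(max_abs_mean_delta_s = 0.10,
                             max_abs_duration_gap_s = 0.10,
                             max_dose_diff_pct = 0.5,
                             enabled = c(delta_on = TRUE, delta_off = TRUE,
                                         duration_gap = TRUE, dose = TRUE)) {
  for (v in c(max_abs_mean_delta_s, max_abs_duration_gap_s, max_dose_diff_pct)) {
    check_number(v, "tolerance", positive = TRUE)
  }
  structure(list(max_abs_mean_delta_s = max_abs_mean_delta_s,
                 max_abs_duration_gap_s = max_abs_duration_gap_s,
                 max_dose_diff_pct = max_dose_diff_pct,
                 enabled = enabled),
            class = "tolerance_policy")
}

#' Evaluate QA metrics against a tolerance policy
#'
#' @param metrics Named list of metric values (seconds or percent):
#'   `delta_on`, `delta_off`, `duration_gap`, `dose` (any may be `NULL` /
#'   missing when the corresponding input was not provided).
#' @param policy A [tolerance_policy()].
#' @return Tibble: `metric`, `value`, `tolerance`, `status` (`"pass"` iff
#'   |value| <= tolerance, `"fail"` otherwise, `"not evaluated"` for
#'   disabled or absent metrics).
#' @export
evaluate_tolerances <- function(metrics, policy = tolerance_policy()) {
  tol <- c(delta_on = policy$max_abs_mean_delta_s,
           delta_off = policy$max_abs_mean_delta_s,
           duration_gap = policy$max_abs_duration_gap_s,
           dose = policy$max_dose_diff_pct)
  purrr::map_dfr(names(tol), function(m) {
    value <- metrics[[m]]
    enabled <- isTRUE(policy$enabled[[m]])
    status <- if (!enabled || is.null(value) || is.na(value)) {
      "not evaluated"
    } else if (abs(value) <= tol[[m]]) "pass" else "fail"
    tibble(metric = m,
           value = if (is.null(value)) NA_real_ else value,
           tolerance = tol[[m]], status = status)
  })
}

#' Run the full QA analysis for one session
#'
#' Orchestrates the whole chain on one gating log: read and validate the
#' log, condition and segment the respiratory signal, detect beam intervals,
#' pair and aggregate, then (when provided) the EPID cine verification and
#' the ion-chamber dose comparison, and finally the tolerance evaluation.
#' The report carries a provenance block (input file hashes, parameters,
#' package version) and is deterministic given inputs and configuration.
#'
#' @param log_path Path to a gating-log CSV.
#' @param epid_dir Optional EPID frame-stack directory
#'   (see [load_cine_frames()]).
#' @param doses_ref,doses_gated Optional ion-chamber dose lists (cGy),
#'   non-gated reference and gated arm.
#' @param policy A [tolerance_policy()].
#' @param window Planned gating window fractions (default `c(0.25, 0.75)`).
#' @param smooth_window,min_prominence,min_separation_fraction,sd_type
#'   Analysis parameters, see [analyze_gating_session()].
#' @param roi A [roi_spec()] for the EPID ROI.
#' @return A `qa_report` object.
#' @export
run_session_qa <- function(log_path, epid_dir = NULL,
                           doses_ref = NULL, doses_gated = NULL,
                           policy = tolerance_policy(),
                           window = c(0.25, 0.75), smooth_window = 5,
                           min_prominence = 0.2,
                           min_separation_fraction = 0.4,
                           sd_type = "population",
                           roi = roi_spec()) {
  log <- read_gating_log(log_path)
  session <- analyze_gating_session(
    log, smooth_window = smooth_window, min_prominence = min_prominence,
    min_separation_fraction = min_separation_fraction, window = window,
    sd_type = sd_type
  )

  epid <- NULL
  if (!is.null(epid_dir)) {
    stack <- load_cine_frames(epid_dir)
    series <- compute_roi_series(stack, roi)
    seg <- detect_beam_on_frames(series)
    dur <- epid_beam_durations(seg$segments, stack$frame_period)
    log_durations <- session$intervals$duration[session$intervals$complete]
    epid <- list(durations = dur$durations, stats = dur$stats,
                 vs_log = compare_epid_vs_log(dur$durations, log_durations))
  }

  dose <- NULL
  if (!is.null(doses_ref) && !is.null(doses_gated)) {
    dose <- dose_comparison(doses_ref, doses_gated,
                            paired = length(doses_ref) == length(doses_gated))
  }

  agg <- function(metric) {
    session$aggregates$mean[session$aggregates$metric == metric]
  }
  dose_diff_pct <- if (!is.null(dose) && "difference" %in% dose$arm) {
    100 * dose$mean[dose$arm == "difference"] /
      dose$mean[dose$arm == "reference"]
  } else NULL
  checks <- evaluate_tolerances(
    list(delta_on = agg("delta_on"), delta_off = agg("delta_off"),
         duration_gap = session$duration_gap, dose = dose_diff_pct),
    policy
  )

  inputs <- c(log = log_path,
              if (!is.null(epid_dir)) {
                c(epid_sidecar = file.path(epid_dir, "sidecar.json"),
                  epid_frames = file.path(epid_dir, "frames.csv"))
              })
  provenance <- list(
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    parameters = list(window = window, smooth_window = smooth_window,
                      min_prominence = min_prominence,
                      min_separation_fraction = min_separation_fraction,
                      sd_type = sd_type),
    policy = unclass(policy)[c("max_abs_mean_delta_s",
                               "max_abs_duration_gap_s",
                               "max_dose_diff_pct")],
    package_version = as.character(utils::packageVersion("gatelog"))
  )
  structure(list(session = session, epid = epid, dose = dose,
                 checks = checks, provenance = provenance),
            class = "qa_report")
}

# JSON-serializable payload, excluding any timestamp, used both by
# render_report and by determinism tests.
report_payload <- function(report) {
  s <- report$session
  list(
    session_id = s$session_id,
    records = s$records,
    aggregates = mutate(s$aggregates,
                        dplyr::across(c("mean", "sd", "median"),
                                      ~ round_half_up(.x, 2))),
    duration_gap = round_half_up(s$duration_gap, 2),
    epid = if (!is.null(report$epid)) {
      list(durations = report$epid$durations,
           stats = mutate(report$epid$stats,
                          dplyr::across(c("mean", "sd", "median"),
                                        ~ round_half_up(.x, 2))),
           vs_log = mutate(report$epid$vs_log,
                           dplyr::across(c("mean", "sd", "median"),
                                         ~ round_half_up(.x, 2))))
    },
    dose = if (!is.null(report$dose)) {
      mutate(report$dose, dplyr::across(c("mean", "sd", "median"),
                                        ~ round_half_up(.x, 2)))
    },
    checks = report$checks,
    provenance = report$provenance
  )
}

#' Render a QA report to files
#'
#' Writes the machine-readable JSON report (full payload plus a `generated`
#' timestamp), the per-cycle CSV table, a summary CSV (one row per metric,
#' per-cycle columns then AVG/STD/Median, the customary QA-table layout,
#' values rounded to 2 decimals half away from zero), and optionally the
#' average-periodic-signal plot.
#'
#' @param report A `qa_report` from [run_session_qa()].
#' @param out_dir Output directory (created if absent).
#' @param formats Subset of `c("json", "csv")`.
#' @param plot Also write `average_signal.pdf` (default `FALSE`).
#' @return Character vector of written file paths, invisibly.
#' @export
render_report <- function(report, out_dir, formats = c("json", "csv"),
                          plot = FALSE) {
  stopifnot(inherits(report, "qa_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  if ("json" %in% formats) {
    path <- file.path(out_dir, "qa_report.json")
    payload <- report_payload(report)
    payload$generated <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    written <- c(written, path)
  }
  if ("csv" %in% formats) {
    rec_path <- file.path(out_dir, "per_cycle.csv")
    readr::write_csv(
      mutate(report$session$records,
             dplyr::across(dplyr::where(is.numeric) & !dplyr::matches("cycle_index"),
                           ~ round_half_up(.x, 2))),
      rec_path
    )
    # Table layout: one row per metric, per-cycle columns, then AVG/STD/Median
    rec <- report$session$records
    wide <- purrr::map_dfr(
      c("delta_on", "delta_off", "window_duration", "trigger_duration"),
      function(m) {
        vals <- round_half_up(rec[[m]], 2)
        st <- aggregate_stats(rec[[m]], report$session$sd_type)
        row <- c(list(metric = m),
                 stats::setNames(as.list(vals),
                                 paste0("cycle_", rec$cycle_index + 1L)),
                 list(AVG = round_half_up(st$mean, 2),
                      STD = round_half_up(st$sd, 2),
                      Median = round_half_up(st$median, 2)))
        as_tibble(row)
      })
    sum_path <- file.path(out_dir, "summary.csv")
    readr::write_csv(wide, sum_path)
    written <- c(written, rec_path, sum_path)
  }
  if (plot) {
    plot_path <- file.path(out_dir, "average_signal.pdf")
    avg <- average_periodic_signal(report$session$signal,
                                   report$session$cycles)
    p <- autoplot(avg, window = report$provenance$parameters$window)
    ggplot2::ggsave(plot_path, p, width = 7, height = 4)
    written <- c(written, plot_path)
  }
  invisible(written)
}

#' @export
print.qa_report <- function(x, ...) {
  cat(sprintf("<qa_report> session \"%s\"\n", x$session$session_id))
  print(x$checks)
  invisible(x)
}
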