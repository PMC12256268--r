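#' Bundled monthly phantom trial deltas
#'
#' Per-cycle timing differences from a three-trial (monthly) motion-phantom
#' reproducibility series on a clinical gating system: for each respiratory
#' cycle, the difference between the planned 25% phase time and the beam-on
#' trigger (`delta_on_s`) and between the 75% phase time and the beam-off
#' trigger (`delta_off_s`), in seconds at 2-decimal precision. Trial 1
#' delivered only 5 cycles; its sixth row is `NA` and should be dropped
#' before aggregation (see [aggregate_stats()]).
#'
#' @return Tibble: `trial`, `cycle`, `delta_on_s`, `delta_off_s`.
#' @export
#' @examples
#' qa_example_trials() |>
#'   dplyr::filter(trial == 1, !is.na(delta_on_s)) |>
#'   dplyr::pull(delta_on_s) |>
#'   aggregate_stats()
qa_example_trials <- function() {
  path <- system.file("extdata", "monthly_trials.csv", package = "gatelog")
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    trial = readr::col_integer(),
                    cycle = readr::col_integer(),
                    delta_on_s = readr::col_double(),
                    delta_off_s = readr::col_double()
                  ))
}
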