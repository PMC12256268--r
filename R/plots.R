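# ggplot2 displays for the result types.

#' Plot an average periodic signal
#'
#' Mean +/- population-SD ribbon of the phase-averaged respiratory signal
#' with the planned gating window shaded.
#'
#' @param object An `avg_periodic_signal` from [average_periodic_signal()].
#' @param window Gating window fractions to shade (default `c(0.25, 0.75)`).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.avg_periodic_signal <- function(object, window = c(0.25, 0.75), ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$phase, y = .data$mean_v)) +
    ggplot2::annotate("rect", xmin = window[1], xmax = window[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_v - .data$sd_v,
                                      ymax = .data$mean_v + .data$sd_v),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "respiratory phase (fraction of cycle)",
      y = "normalized AP amplitude",
      title = sprintf("Average periodic signal (%d cycles)",
                      attr(object, "n_cycles")),
      subtitle = sprintf("shaded band: planned %g%%-%g%% gating window",
                         100 * window[1], 100 * window[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot a session's signal with phase marks and beam triggers
#'
#' The conditioned respiratory signal with each cycle's planned 25%/75%
#' phase points marked and the beam-on intervals overlaid, the standard
#' visual check that triggers sit on the window edges.
#'
#' @param object A `qa_session` from [analyze_gating_session()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.qa_session <- function(object, ...) {
  rec <- object$records
  ph <- tidyr::pivot_longer(rec[c("cycle_index", "t25", "t75")],
                            c("t25", "t75"),
                            names_to = "edge", values_to = "time")
  ph$v <- stats::approx(object$signal$t, object$signal$v, xout = ph$time,
                        rule = 2)$y
  ggplot2::ggplot(object$signal, ggplot2::aes(x = .data$t, y = .data$v)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::annotate("rect", xmin = rec$t_on, xmax = rec$t_off,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red") +
    ggplot2::geom_point(data = ph, ggplot2::aes(x = .data$time, y = .data$v),
                        colour = "red", shape = 8, size = 2) +
    ggplot2::labs(
      x = "time (s)", y = "normalized AP amplitude",
      title = sprintf("Session \"%s\": phase window vs beam triggers",
                      object$session_id),
      subtitle = "stars: planned 25%/75% phase points; shaded: beam on"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a reproducibility trend
#'
#' Per-session metric means with +/- SD error bars across a QA series.
#'
#' @param object A `qa_trend` from [reproducibility_trend()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.qa_trend <- function(object, ...) {
  ggplot2::ggplot(object$per_session,
                  ggplot2::aes(x = .data$session_id, y = .data$mean,
                               group = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "seconds",
                  title = "Multi-session reproducibility") +
    ggplot2::theme_minimal()
}
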