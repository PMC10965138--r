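#' Plot a parameter time trace
#'
#' Line plot of a [time_trace()] with the protocol's load window marked.
#'
#' @param object A `time_trace`.
#' @param windows Optional [protocol_windows()] for load markers.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.time_trace <- function(object, windows = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                            y = .data$value)) +
    ggplot2::geom_line(color = "#2c5f8a") +
    ggplot2::labs(x = "time (s)", y = attr(object, "parameter") %||% "value")
  if (!is.null(windows)) {
    p <- p + ggplot2::geom_vline(xintercept = windows$load,
                                 linetype = "dashed")
  }
  p + ggplot2::theme_minimal()
}

#' Plot a correlation curve
#'
#' g2 against lag on a log-tau axis.
#'
#' @param object A [correlation_curve()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.correlation_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$tau_s, y = .data$g2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau ~ "(s)"), y = expression(g[2](tau))) +
    ggplot2::theme_minimal()
}

#' Plot titration percent changes with linear trends
#'
#' The validation figure: per-parameter percent change from baseline
#' against titration step (or stirrer speed for the flow titration), with
#' least-squares trend lines.
#'
#' @param data Recovered titration tibble ([recover_titration()] layout).
#' @return A ggplot object.
#' @export
plot_titration <- function(data) {
  long <- data |>
    tidyr::pivot_longer(dplyr::all_of(titration_parameters),
                        names_to = "parameter", values_to = "value") |>
    group_by(.data$titration, .data$parameter) |>
    arrange(.data$step, .by_group = TRUE) |>
    mutate(change_pct = percent_change_from_baseline(.data$value)) |>
    ungroup()
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$change_pct,
                                     color = .data$parameter)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::facet_wrap(~ .data$titration, scales = "free_y") +
    ggplot2::labs(x = "titration step", y = "change from baseline (%)") +
    ggplot2::theme_minimal()
}

#' Plot activation features over a filtered session
#'
#' Normalized filtered traces for the six parameters with the detected
#' activation events marked per region.
#'
#' @param params Processed parameter tibble ([process_stream()]).
#' @param analysis Result of [analyze_session()] on the same table.
#' @param config The [run_config()] used.
#' @return A ggplot object.
#' @export
plot_session <- function(params, analysis, config = run_config()) {
  traces <- purrr::imap_dfr(parameter_polarities, function(pol, p) {
    tr <- time_trace(params$time_s, params[[p]], parameter = p)
    filt <- lowpass(tr, config$lowpass_cutoff_hz, config$filter_order,
                    config$zero_phase)
    bl <- baseline_value(filt, config$windows$baseline_average)
    tibble(time_s = filt$time_s, value = filt$value / bl, parameter = p)
  })
  ev <- analysis$features |> filter(.data$found)
  p <- ggplot2::ggplot(traces, ggplot2::aes(x = .data$time_s,
                                            y = .data$value)) +
    ggplot2::geom_line(color = "#2c5f8a") +
    ggplot2::geom_vline(xintercept = config$windows$load,
                        linetype = "dashed") +
    ggplot2::facet_wrap(~ .data$parameter, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "normalized to baseline") +
    ggplot2::theme_minimal()
  if (nrow(ev) > 0) {
    p <- p + ggplot2::geom_point(
      data = ev |> mutate(value = 1 + .data$percent_change / 100),
      ggplot2::aes(x = .data$event_time_s, y = .data$value),
      color = "#c03a2b", size = 2)
  }
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
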