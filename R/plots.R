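#' Plot a strategy audit
#'
#' Bar chart of each null policy's mean percent correct per session length,
#' with the certification ceiling drawn as a dashed line.
#'
#' @param object A `strategy_audit` from [audit_generator()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.strategy_audit <- function(object, ...) {
  ggplot2::ggplot(
    object$results,
    ggplot2::aes(x = .data$policy, y = .data$mean_pct_correct,
                 fill = factor(.data$session_length))
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = object$ceiling, linetype = "dashed") +
    ggplot2::labs(
      x = NULL, y = "mean % correct", fill = "trials/block",
      title = sprintf(
        "Null-strategy audit: %s (ceiling %g%%)",
        if (object$certified) "certified" else "NOT certified", object$ceiling
      )
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a score-method concordance fit
#'
#' Scatter of the paired scores with the unity line (dashed), the refit
#' regression line, and outliers drawn as open circles.
#'
#' @param object A `maze_concordance` from [concordance()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.maze_concordance <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$outlier), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                labels = c("kept", "outlier"), name = NULL) +
    ggplot2::labs(
      x = "score, method 1 (%)", y = "score, method 2 (%)",
      title = sprintf("slope = %.2f, intercept = %.2f%%, R² = %.2f",
                      object$slope, object$intercept, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot rolling learning curves
#'
#' One line per animal plus the across-animal mean (thick black line), with
#' phase boundaries shaded in the background.
#'
#' @param daily A [daily_scores()] tibble.
#' @return A ggplot.
#' @export
plot_learning_curves <- function(daily) {
  phase_spans <- daily |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(from = min(.data$day), to = max(.data$day),
                     .groups = "drop")
  mean_curve <- daily |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(pct_rolling = mean(.data$pct_rolling, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(daily, ggplot2::aes(x = .data$day, y = .data$pct_rolling)) +
    ggplot2::geom_rect(
      data = phase_spans[phase_spans$phase %% 2 == 0, ],
      ggplot2::aes(xmin = .data$from - 0.5, xmax = .data$to + 0.5,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey92"
    ) +
    ggplot2::geom_line(ggplot2::aes(group = .data$animal,
                                    colour = .data$animal), alpha = 0.7) +
    ggplot2::geom_line(data = mean_curve, linewidth = 1.1, colour = "black") +
    ggplot2::labs(x = "training day", y = "% correct (3-day rolling)",
                  colour = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}

#' Plot reaction-time densities
#'
#' Density of reaction times by outcome class, faceted by phase, with dotted
#' vertical lines at the histogram-mode estimates.
#'
#' @param trials A trial tibble.
#' @param phases Phases to include (default the full task, 5-7).
#' @param bin_ms Bin width passed to the mode estimator.
#' @return A ggplot.
#' @export
plot_rt_density <- function(trials, phases = 5:7, bin_ms = 100) {
  rt <- trials |>
    dplyr::filter(.data$phase %in% phases, .data$outcome != "TIMEOUT",
                  !is.na(.data$reaction_time_ms))
  modes <- rt_summaries(trials, phases = phases, bin_ms = bin_ms)
  ggplot2::ggplot(rt, ggplot2::aes(x = .data$reaction_time_ms,
                                   colour = .data$outcome)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(
      data = modes,
      ggplot2::aes(xintercept = .data$mode_ms, colour = .data$outcome),
      linetype = "dotted"
    ) +
    ggplot2::facet_wrap(~phase, ncol = 1, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "reaction time (ms)", y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}
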