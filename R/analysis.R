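#' Score-method concordance regression with outlier rejection
#'
#' Regresses one scoring method's per-animal-per-phase mean scores on
#' another's in exactly two passes: an initial ordinary least-squares fit, an
#' outlier-marking step — points whose distance from that fit exceeds
#' `sd_mult` (3 by default) times the standard deviation of the absolute
#' residuals are flagged — and a single refit through the remaining points.
#' Note the threshold scale is the SD of |residuals|, not the residual SD,
#' and there is no iteration: one marking pass, one refit.
#'
#' @param data A data frame of paired scores.
#' @param x,y Columns (tidy-eval) holding the two methods' scores, in percent.
#' @param sd_mult Outlier threshold multiplier.
#' @return A `maze_concordance`: list with `slope`, `intercept`, `r_squared`,
#'   `p_value` (slope test of the refit), `outlier` mask, `n_points`,
#'   `n_outliers`, the refit `fit` (an `lm`), the `first_fit`, and `data`
#'   (tibble of `x`, `y`, `outlier`). At least 3 points are required, and an
#'   error is raised if every point is marked as an outlier.
#' @examples
#' d <- data.frame(m = c(50, 60, 70, 80, 90), r = c(51, 59, 70, 81, 89))
#' glance(concordance(d, m, r))
#' @export
concordance <- function(data, x, y, sd_mult = 3) {
  xv <- eval_tidy(enquo(x), data)
  yv <- eval_tidy(enquo(y), data)
  keep <- !is.na(xv) & !is.na(yv)
  xv <- xv[keep]
  yv <- yv[keep]
  if (length(xv) < 3) abort("concordance needs at least 3 complete points")
  d <- tibble(x = xv, y = yv)
  fit1 <- lm(y ~ x, data = d)
  abs_res <- abs(resid(fit1))
  s <- sd(abs_res)
  outlier <- abs_res > sd_mult * s
  if (all(outlier)) abort("all points marked as outliers; degenerate fit")
  fit2 <- lm(y ~ x, data = d[!outlier, ])
  sm <- suppressWarnings(summary(fit2))   # exact agreement trips lm's
                                          # "essentially perfect fit" warning
  structure(
    list(
      slope = unname(coef(fit2)[2]),
      intercept = unname(coef(fit2)[1]),
      r_squared = sm$r.squared,
      p_value = unname(sm$coefficients[2, 4]),
      outlier = outlier,
      n_points = length(xv),
      n_outliers = sum(outlier),
      sd_mult = sd_mult,
      fit = fit2,
      first_fit = fit1,
      data = dplyr::mutate(d, outlier = outlier)
    ),
    class = "maze_concordance"
  )
}

#' @export
print.maze_concordance <- function(x, ...) {
  cat(sprintf(
    "<maze_concordance> slope = %.3f, intercept = %.3f%%, R^2 = %.3f, p = %.3g\n  %d points, %d outlier(s) removed (> %g SD of |residuals|)\n",
    x$slope, x$intercept, x$r_squared, x$p_value,
    x$n_points, x$n_outliers, x$sd_mult
  ))
  invisible(x)
}

#' @rdname concordance
#' @param x A `maze_concordance` (for the `tidy`/`glance` methods).
#' @param ... Unused.
#' @export
tidy.maze_concordance <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(
    term = rownames(sm),
    estimate = sm[, 1], std.error = sm[, 2],
    statistic = sm[, 3], p.value = sm[, 4]
  )
}

#' @rdname concordance
#' @export
glance.maze_concordance <- function(x, ...) {
  tibble(
    slope = x$slope, intercept = x$intercept, r.squared = x$r_squared,
    p.value = x$p_value, n_points = x$n_points, n_outliers = x$n_outliers
  )
}

#' Reaction-time distribution summaries
#'
#' Summarizes reaction times by phase and outcome class for the full-task
#' phases (5-7 by default; earlier phases are excluded because their sensor
#' readings are unreliable). Timed-out trials are excluded from every
#' distribution: their "reaction time" is just the timeout threshold and not
#' animal behavior. The mode is estimated as the midpoint of the tallest
#' fixed-width histogram bin (100 ms by default) and the spread as the
#' interquartile range with linear interpolation between order statistics
#' (quantile type 7).
#'
#' @param trials A trial tibble with `phase`, `outcome`, `reaction_time_ms`.
#' @param phases Phases to include.
#' @param bin_ms Histogram bin width for the mode estimate.
#' @param by_phase Summarise per phase (`TRUE`) or pooled across the included
#'   phases (`FALSE`).
#' @return A tibble with `phase` (unless pooled), `outcome`, `n_trials`,
#'   `mode_ms`, `q25_ms`, `q75_ms`, `iqr_ms` and a `samples` list-column.
#' @examples
#' trials <- simulate_training(n_animals = 1,
#'                             schedule = training_schedule()[40:45, ],
#'                             seed = 8)
#' rt_summaries(trials)
#' @export
rt_summaries <- function(trials, phases = 5:7, bin_ms = 100, by_phase = TRUE) {
  rt <- trials |>
    dplyr::filter(.data$phase %in% phases, .data$outcome != "TIMEOUT",
                  !is.na(.data$reaction_time_ms))
  if (nrow(rt) == 0) abort("no non-timeout trials in the requested phases")
  groups <- if (by_phase) c("phase", "outcome") else "outcome"
  rt |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      mode_ms = hist_mode(.data$reaction_time_ms, bin_ms),
      q25_ms = unname(quantile(.data$reaction_time_ms, 0.25, type = 7)),
      q75_ms = unname(quantile(.data$reaction_time_ms, 0.75, type = 7)),
      samples = list(.data$reaction_time_ms),
      .groups = "drop"
    ) |>
    dplyr::mutate(iqr_ms = .data$q75_ms - .data$q25_ms,
                  .after = "q75_ms")
}

# histogram-peak mode: midpoint of the tallest bin on a fixed grid from 0;
# ties break toward the earliest bin
hist_mode <- function(x, bin_ms = 100) {
  breaks <- seq(0, (max(x) %/% bin_ms + 1) * bin_ms, by = bin_ms)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  breaks[which.max(counts)] + bin_ms / 2
}

#' Compare two reaction-time samples
#'
#' Two-sided two-sample Kolmogorov-Smirnov test via [stats::ks.test()],
#' using the exact p-value when both samples have fewer than 30 observations
#' and the asymptotic distribution otherwise.
#'
#' @param a,b Numeric samples (each of size >= 2).
#' @return A one-row tibble: `statistic` (the KS D), `p_value`, `n_a`, `n_b`,
#'   `method`.
#' @examples
#' rt_compare(rlnorm(50, 7, 0.3), rlnorm(50, 7.3, 0.3))
#' @export
rt_compare <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    abort("each sample needs at least 2 observations")
  }
  exact <- length(a) < 30 && length(b) < 30
  kt <- suppressWarnings(ks.test(a, b, alternative = "two.sided",
                                 exact = exact))
  tibble(
    statistic = unname(kt$statistic),
    p_value = kt$p.value,
    n_a = length(a), n_b = length(b),
    method = if (exact) "exact" else "asymptotic"
  )
}
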