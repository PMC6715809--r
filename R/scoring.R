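#' Reward-count trial scoring
#'
#' Scores a trial from the number of pellets rewarded: `CORRECT` iff the
#' pellet count reaches the phase threshold — 3 or more in phase 1, 2 or more
#' in phases 2-5, 1 or more in phases 6-7. A hint trial where the animal only
#' collected the single hint pellet therefore scores `INCORRECT` in phases
#' 1-2, which is what separates reward scoring from raw sensor scoring early
#' in training.
#'
#' @param pellets Integer pellet counts (>= 0).
#' @param phase Phase number(s) 1-7, recycled against `pellets`.
#' @return Character vector, `"CORRECT"`/`"INCORRECT"`.
#' @examples
#' reward_score(c(3, 1, 1), c(1, 5, 6))
#' @export
reward_score <- function(pellets, phase) {
  if (any(!phase %in% 1:7)) abort("`phase` must be in 1..7")
  if (any(pellets < 0, na.rm = TRUE)) abort("`pellets` must be non-negative")
  thr <- c(3L, 2L, 2L, 2L, 2L, 1L, 1L)[phase]
  ifelse(pellets >= thr, "CORRECT", "INCORRECT")
}

#' Sensor-based trial scoring
#'
#' Scores a trial from the reward-area sensors: `CORRECT` iff the first
#' sensor crossed is at the cued side; timed-out trials (no crossing) are
#' scored `INCORRECT`. Sensor scores are unreliable in phases 1-4 because in
#' the compact maze the rat's tail could trip a sensor; [daily_scores()]
#' flags those phases.
#'
#' @param chosen_side First sensor side per trial (`NA` for timeouts).
#' @param cued_side Cued side per trial.
#' @return Character vector, `"CORRECT"`/`"INCORRECT"`.
#' @examples
#' sensor_score(c("L", "R", NA), c("L", "L", "L"))
#' @export
sensor_score <- function(chosen_side, cued_side) {
  ifelse(!is.na(chosen_side) & chosen_side == as_side(cued_side),
         "CORRECT", "INCORRECT")
}

#' Score trials by one of the three methods
#'
#' Adds a logical `correct` column to a trial tibble using one of:
#' * `"manual"` — the manual-equivalent score: the trial's outcome was
#'   `CORRECT` and the response came before any hint (timeouts incorrect);
#' * `"reward"` — [reward_score()] on the pellet count;
#' * `"sensor"` — [sensor_score()] on the first sensor crossing.
#'
#' Hint trials can be excluded (`exclude_hints`); manual scoring excludes
#' them by default, while reward and sensor scoring keep them by default so
#' the early-phase divergence between the methods is visible.
#'
#' @param trials A trial tibble (from [run_session()], [simulate_training()]
#'   or [trial_records_from_events()]) with columns `phase`, `cued_side`,
#'   `chosen_side`, `pellets`, `outcome`, `is_hint`, `responded_pre_hint`.
#' @param method `"manual"`, `"reward"` or `"sensor"`.
#' @param exclude_hints Drop hint trials before scoring; default `TRUE` for
#'   `"manual"`, `FALSE` otherwise.
#' @return The filtered tibble with `method` and `correct` columns added.
#' @export
score_trials <- function(trials, method = c("manual", "reward", "sensor"),
                         exclude_hints = NULL) {
  method <- match.arg(method)
  if (is.null(exclude_hints)) exclude_hints <- method == "manual"
  if (exclude_hints) trials <- dplyr::filter(trials, !.data$is_hint)
  correct <- switch(method,
    manual = trials$outcome == "CORRECT" &
      !is.na(trials$responded_pre_hint) & trials$responded_pre_hint,
    reward = reward_score(trials$pellets, trials$phase) == "CORRECT",
    sensor = sensor_score(trials$chosen_side, trials$cued_side) == "CORRECT"
  )
  dplyr::mutate(trials, method = method, correct = correct)
}

#' Trailing rolling mean of a daily score series
#'
#' A trailing window mean with partial windows at the start of the series
#' (day 1 uses day 1 alone, day 2 the first two days, ...), so learning
#' curves span every training day. `NA` days are dropped from their windows.
#'
#' @param x Numeric series (e.g. daily percent correct).
#' @param window Window length in days (default 3).
#' @return Numeric vector, same length as `x`.
#' @examples
#' rolling_curve(c(60, 70, 80))
#' @export
rolling_curve <- function(x, window = 3) {
  stopifnot(window >= 1)
  if (length(x) == 0) abort("empty series")
  zoo::rollapplyr(x, window, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, partial = TRUE)
}

#' Daily percent-correct series with a rolling learning curve
#'
#' Aggregates scored trials to one row per animal-day: percent correct,
#' trial count, and the trailing rolling average over `window` days
#' (computed within animal, across the full day series). For sensor scoring
#' a `sensor_reliable` flag marks phases 5-7; a warning is issued when
#' unreliable phases (1-4) are present.
#'
#' @inheritParams score_trials
#' @param window Rolling window in days.
#' @return A tibble: `animal`, `day`, `phase`, `method`, `n_trials`,
#'   `pct_correct`, `pct_rolling` (and `sensor_reliable` for sensor scoring).
#' @examples
#' trials <- simulate_training(n_animals = 1,
#'                             schedule = training_schedule()[1:4, ],
#'                             seed = 2)
#' daily_scores(trials, "reward")
#' @export
daily_scores <- function(trials, method = c("manual", "reward", "sensor"),
                         exclude_hints = NULL, window = 3) {
  method <- match.arg(method)
  scored <- score_trials(trials, method, exclude_hints)
  daily <- scored |>
    dplyr::group_by(.data$animal, .data$day, .data$phase, .data$method) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      pct_correct = 100 * mean(.data$correct),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$animal, .data$day)
  daily <- daily |>
    dplyr::group_by(.data$animal) |>
    dplyr::mutate(pct_rolling = rolling_curve(.data$pct_correct, window)) |>
    dplyr::ungroup()
  if (method == "sensor") {
    daily <- dplyr::mutate(daily, sensor_reliable = .data$phase >= 5)
    if (any(!daily$sensor_reliable)) {
      warn(paste(
        "sensor scores are unreliable for phases 1-4:",
        "in the compact maze the rat's tail can trip the reward-area sensors"
      ))
    }
  }
  daily
}

#' Per-animal per-phase mean scores
#'
#' Pools an animal's scored trials over the days of each phase (the points
#' of the score-concordance scatter: one per animal per phase).
#'
#' @param daily A [daily_scores()] tibble.
#' @return A tibble `animal`, `phase`, `method`, `n_trials`, `mean_pct`.
#' @export
phase_means <- function(daily) {
  daily |>
    dplyr::group_by(.data$animal, .data$phase, .data$method) |>
    dplyr::summarise(
      mean_pct = stats::weighted.mean(.data$pct_correct, .data$n_trials),
      n_trials = sum(.data$n_trials),
      .groups = "drop"
    )
}
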