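#' Write and read JSON-lines event logs
#'
#' The canonical on-disk record of a session: a header line with the phase
#' configuration and seeds, then one JSON object per event:
#' `{"t_ms":..,"trial":..,"block":..,"kind":..,"payload":{..}}`. Payloads are
#' kind-specific: `tone_hz` for `CUE_ON`, `side`/`pellets` for dispenses,
#' `side` for sensor crossings, `outcome`/`is_hint` for `TRIAL_END`.
#'
#' @param session A `maze_session` from [run_session()].
#' @param path Output file path.
#' @return `write_event_log()` returns `path` invisibly. `read_event_log()`
#'   returns a list with `header` (named list) and `events` (tibble in the
#'   same shape [run_session()] produces).
#' @examples
#' s <- run_session(1, function(cued, ctx) list(choice = cued, latency_ms = 700),
#'                  seed = 9)
#' p <- tempfile(fileext = ".jsonl")
#' write_event_log(s, p)
#' log <- read_event_log(p)
#' log$header$phase
#' @export
write_event_log <- function(session, path) {
  stopifnot(inherits(session, "maze_session"))
  cfg <- unclass(session$config)
  header <- jsonlite::toJSON(
    list(
      type = "header", animal = session$animal_id, day = session$day,
      day_in_phase = session$day_in_phase, phase = cfg$phase,
      seed = session$seed, block_seeds = session$block_seeds, config = cfg
    ),
    auto_unbox = TRUE, digits = NA
  )
  ev <- session$events
  lines <- character(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    payload <- list()
    if (!is.na(ev$tone_hz[i])) payload$tone_hz <- ev$tone_hz[i]
    if (!is.na(ev$side[i])) payload$side <- ev$side[i]
    if (!is.na(ev$pellets[i])) payload$pellets <- ev$pellets[i]
    if (!is.na(ev$outcome[i])) payload$outcome <- ev$outcome[i]
    if (!is.na(ev$is_hint[i])) payload$is_hint <- ev$is_hint[i]
    lines[i] <- jsonlite::toJSON(
      list(t_ms = ev$t_ms[i], trial = ev$trial[i], block = ev$block[i],
           kind = ev$kind[i], payload = payload),
      auto_unbox = TRUE, digits = NA
    )
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) abort("empty event log")
  header <- jsonlite::fromJSON(lines[1], simplifyVector = TRUE)
  if (!identical(header$type, "header")) {
    abort("first line of an event log must be the session header")
  }
  parsed <- purrr::map(lines[-1], jsonlite::fromJSON, simplifyVector = TRUE)
  pick <- function(e, field, default) {
    v <- e$payload[[field]]
    if (is.null(v)) default else v
  }
  events <- tibble(
    t_ms = purrr::map_dbl(parsed, "t_ms"),
    trial = purrr::map_int(parsed, ~ as.integer(.x$trial)),
    block = purrr::map_int(parsed, ~ as.integer(.x$block)),
    kind = purrr::map_chr(parsed, "kind"),
    side = purrr::map_chr(parsed, pick, "side", NA_character_),
    pellets = purrr::map_int(parsed, ~ as.integer(pick(.x, "pellets", NA_integer_))),
    tone_hz = purrr::map_dbl(parsed, ~ as.numeric(pick(.x, "tone_hz", NA_real_))),
    outcome = purrr::map_chr(parsed, pick, "outcome", NA_character_),
    is_hint = purrr::map_lgl(parsed, ~ as.logical(pick(.x, "is_hint", NA)))
  )
  list(header = header, events = events)
}

#' Reconstruct per-trial records from an event log
#'
#' Rebuilds the per-trial summary (cued side, chosen side, reaction time,
#' pellets, outcome) from raw events alone, so the JSONL log is lossless for
#' scoring purposes. The cued side is decoded from the `CUE_ON` tone via the
#' configuration's tone map; the reaction time is the first reward-area
#' sensor timestamp minus the nose-poke timestamp; pellets are the feeder
#' dispense plus the hint pellet when the animal ended at the cued side.
#'
#' @param events An events tibble (from a session or [read_event_log()]).
#' @param config The session's [phase_config()] (tone map, thresholds).
#' @return A tibble of trial records (one row per block x trial).
#' @export
trial_records_from_events <- function(events, config) {
  stopifnot(inherits(config, "phase_config"))
  events |>
    dplyr::group_by(.data$block, .data$trial) |>
    dplyr::arrange(.data$t_ms, .by_group = TRUE) |>
    dplyr::summarise(
      t_start = .data$t_ms[.data$kind == "NOSE_POKE"][1],
      cued_side = side_for_tone(config, .data$tone_hz[.data$kind == "CUE_ON"][1]),
      chosen_side = {
        s <- .data$side[.data$kind %in% c("SENSOR_LEFT", "SENSOR_RIGHT")]
        if (length(s)) s[1] else NA_character_
      },
      reaction_time_ms = {
        st <- .data$t_ms[.data$kind %in% c("SENSOR_LEFT", "SENSOR_RIGHT")]
        if (length(st)) st[1] - .data$t_ms[.data$kind == "NOSE_POKE"][1] else NA_real_
      },
      hint_given = any(.data$kind == "HINT_DISPENSE"),
      feeder_pellets = sum(.data$pellets[.data$kind == "FEEDER_DISPENSE"],
                           na.rm = TRUE),
      timed_out = any(.data$kind == "TIMEOUT"),
      is_hint = .data$is_hint[.data$kind == "TRIAL_END"][1],
      t_end = .data$t_ms[.data$kind == "TRIAL_END"][1],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pellets = as.integer(
        .data$feeder_pellets +
          (.data$hint_given & !is.na(.data$chosen_side) &
             .data$chosen_side == .data$cued_side)
      ),
      outcome = dplyr::case_when(
        .data$timed_out ~ "TIMEOUT",
        .data$chosen_side == .data$cued_side ~ "CORRECT",
        TRUE ~ "INCORRECT"
      ),
      responded_pre_hint = dplyr::if_else(
        .data$timed_out, NA, !.data$hint_given | !.data$is_hint
      ),
      trial_index = .data$trial
    ) |>
    dplyr::select(
      "block", "trial_index", "cued_side", "chosen_side", "reaction_time_ms",
      "pellets", "outcome", "is_hint", "responded_pre_hint", "t_start", "t_end"
    )
}
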