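#' Per-phase task configuration
#'
#' Training is divided into seven phases of increasing maze size and
#' difficulty. Phases 1-4 are cue training in a compact configuration; from
#' phase 5 the arms move back (20/50/80 cm central arm) and the task gains a
#' working-memory component. Defaults follow the training protocol: blocks of
#' 10 trials in phase 1, 15 in phases 2-5, 20 in phase 6, 25 in phase 7; four
#' blocks per session; a correct pre-hint response pays 3 pellets in phase 1,
#' 2 in phases 2-5 and 1 in phases 6-7 (the same counts serve as the
#' reward-scoring thresholds); 6 s trial timeout in phases 1-4, scaled up with
#' the arm length to 8 s and 10 s in phases 6-7 (per-phase timeouts beyond
#' phase 1 are a configurable stand-in); hint trials in phases 1-2 with a
#' hint delay ramping from 0 to 2 s across early phase-1 sessions; cue tones
#' 7 Hz for left and 14 Hz for right by default (counterbalance per subject
#' via the `tone_hz_*` overrides).
#'
#' @param phase Integer 1-7.
#' @param ... Named overrides of any default field.
#' @return A `phase_config` list.
#' @examples
#' phase_config(7)
#' phase_config(1, hint_fraction = 0.5)$hint_fraction
#' @export
phase_config <- function(phase, ...) {
  stopifnot(length(phase) == 1, phase %in% 1:7)
  phase <- as.integer(phase)
  cfg <- list(
    phase = phase,
    trials_per_block = c(10L, 15L, 15L, 15L, 15L, 20L, 25L)[phase],
    blocks_per_session = 4L,
    pellets_correct = c(3L, 2L, 2L, 2L, 2L, 1L, 1L)[phase],
    pellet_threshold = c(3L, 2L, 2L, 2L, 2L, 1L, 1L)[phase],
    timeout_ms = c(6000, 6000, 6000, 6000, 6000, 8000, 10000)[phase],
    hint_enabled = phase <= 2L,
    hint_fraction = c(0.15, 0.10, 0, 0, 0, 0, 0)[phase],
    hint_full_days = if (phase == 1L) 2L else 0L,
    hint_delay_max_ms = 2000,
    hint_delay_ramp_days = 5L,
    central_arm_cm = c(0, 0, 0, 0, 20, 50, 80)[phase],
    tone_hz_left = 7,
    tone_hz_right = 14,
    interblock_gap_ms = 300000
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) abort(paste0("unknown phase_config field(s): ",
                                paste(bad, collapse = ", ")))
  cfg[names(dots)] <- dots
  structure(cfg, class = "phase_config")
}

#' @export
print.phase_config <- function(x, ...) {
  cat(sprintf(
    "<phase_config> phase %d: %d trials x %d blocks, timeout %g ms, %d pellet(s) on correct,\n  threshold %d, hints %s, central arm %g cm, tones L=%g Hz R=%g Hz\n",
    x$phase, x$trials_per_block, x$blocks_per_session, x$timeout_ms,
    x$pellets_correct, x$pellet_threshold,
    if (x$hint_enabled) "on" else "off", x$central_arm_cm,
    x$tone_hz_left, x$tone_hz_right
  ))
  invisible(x)
}

# Hint delay ramps linearly from 0 to hint_delay_max_ms over the first
# hint_delay_ramp_days sessions of the phase.
hint_delay_for <- function(config, day_in_phase = 1) {
  if (!config$hint_enabled) return(Inf)
  ramp <- max(1L, config$hint_delay_ramp_days)
  min(1, (day_in_phase - 1) / ramp) * config$hint_delay_max_ms
}

# Fraction of trials that are hint trials: every trial during the first
# hint_full_days sessions, then the baseline hint_fraction.
hint_fraction_for <- function(config, day_in_phase = 1) {
  if (!config$hint_enabled) return(0)
  if (day_in_phase <= config$hint_full_days) 1 else config$hint_fraction
}

tone_for_side <- function(config, side) {
  ifelse(side == "L", config$tone_hz_left, config$tone_hz_right)
}

side_for_tone <- function(config, tone_hz) {
  out <- rep(NA_character_, length(tone_hz))
  out[tone_hz == config$tone_hz_left] <- "L"
  out[tone_hz == config$tone_hz_right] <- "R"
  out
}

empty_events <- function() {
  tibble(
    t_ms = numeric(), trial = integer(), block = integer(), kind = character(),
    side = character(), pellets = integer(), tone_hz = numeric(),
    outcome = character(), is_hint = logical()
  )
}

# Core trial state machine on plain vectors (hot path). `respond` is
# function(cued_side, ctx) -> list(choice, latency_ms) or NULL.
run_trial_core <- function(cued_side, config, respond, t0 = 0,
                           trial = 1L, block = 1L,
                           is_hint = FALSE, hint_delay_ms = 0,
                           ctx_extra = list()) {
  timeout <- config$timeout_ms
  ctx <- c(list(
    phase = config$phase, trial_index = trial, block = block,
    is_hint = is_hint, hint_delay_ms = hint_delay_ms,
    timeout_ms = timeout
  ), ctx_extra)
  resp <- respond(cued_side, ctx)
  responded <- !is.null(resp)
  if (responded) {
    if (is.null(resp$latency_ms) || resp$latency_ms < 0) {
      abort("subject callback returned a negative or missing latency")
    }
    choice <- as_side(resp$choice)
    latency <- as.numeric(resp$latency_ms)
    if (latency > timeout) responded <- FALSE   # too slow: trial times out
  }
  hint_given <- is_hint && hint_delay_ms <= timeout &&
    (!responded || latency > hint_delay_ms)
  pre_hint <- responded && (!is_hint || latency <= hint_delay_ms)

  ev_t <- c(t0, t0)
  ev_kind <- c("NOSE_POKE", "CUE_ON")
  ev_side <- c(NA_character_, NA_character_)
  ev_pellets <- c(NA_integer_, NA_integer_)
  ev_tone <- c(NA_real_, tone_for_side(config, cued_side))
  add <- function(t, kind, side = NA_character_, pellets = NA_integer_,
                  tone = NA_real_) {
    ev_t <<- c(ev_t, t)
    ev_kind <<- c(ev_kind, kind)
    ev_side <<- c(ev_side, side)
    ev_pellets <<- c(ev_pellets, pellets)
    ev_tone <<- c(ev_tone, tone)
  }
  if (hint_given) {
    add(t0 + hint_delay_ms, "HINT_DISPENSE", side = cued_side, pellets = 1L)
  }
  if (responded) {
    correct <- choice == cued_side
    add(t0 + latency,
        if (choice == "L") "SENSOR_LEFT" else "SENSOR_RIGHT", side = choice)
    pellets <- 0L
    if (pre_hint && correct) {
      pellets <- config$pellets_correct
      add(t0 + latency, "FEEDER_DISPENSE", side = choice, pellets = pellets)
    } else if (!pre_hint && correct) {
      pellets <- 1L   # the hint pellet, collected at the cued side
    }
    t_end <- t0 + latency
    outcome <- if (correct) "CORRECT" else "INCORRECT"
  } else {
    add(t0 + timeout, "TIMEOUT")
    pellets <- 0L
    t_end <- t0 + timeout
    outcome <- "TIMEOUT"
    choice <- NA_character_
    latency <- NA_real_
  }
  ev_t <- c(ev_t, t_end)
  ev_kind <- c(ev_kind, "TRIAL_END")
  ev_side <- c(ev_side, NA_character_)
  ev_pellets <- c(ev_pellets, NA_integer_)
  ev_tone <- c(ev_tone, NA_real_)
  n_ev <- length(ev_t)

  list(
    record = list(
      trial_index = trial, cued_side = cued_side, chosen_side = choice,
      reaction_time_ms = latency, pellets = pellets, outcome = outcome,
      is_hint = is_hint, responded_pre_hint = if (responded) pre_hint else NA,
      t_start = t0, t_end = t_end
    ),
    events = list(
      t_ms = ev_t, trial = rep(trial, n_ev), block = rep(block, n_ev),
      kind = ev_kind, side = ev_side, pellets = ev_pellets, tone_hz = ev_tone,
      outcome = c(rep(NA_character_, n_ev - 1L), outcome),
      is_hint = c(rep(NA, n_ev - 1L), is_hint)
    ),
    t_end = t_end
  )
}

#' Run a single trial through the state machine
#'
#' A trial starts when the nose-poke sensors fire (time `t0`), which triggers
#' the cue tone. The subject callback returns a chosen side and latency (or
#' `NULL` for no response). If the latency is within the phase timeout a
#' reward-area sensor event is emitted at `t0 + latency` and, when the choice
#' is correct and pre-hint, the feeder dispenses the phase's pellet count;
#' otherwise a `TIMEOUT` event fires at `t0 + timeout_ms`. On hint trials one
#' pellet is dispensed at the cued side after the hint delay unless the
#' subject has already responded; a subject that responds only after the hint
#' collects that single pellet at best. Timed-out trials end with 0 pellets.
#'
#' @param cued_side The scheduled side, `"L"` or `"R"`.
#' @param config A [phase_config()].
#' @param subject A callback `function(cued_side, ctx)` returning
#'   `list(choice =, latency_ms =)` or `NULL`; `ctx` carries phase, timeout,
#'   hint flag and hint delay.
#' @param t0 Trial start time, ms from session start.
#' @param trial,block 1-based indices stamped into events.
#' @param is_hint Whether this is a hint trial.
#' @param hint_delay_ms Delay from cue to hint dispense.
#' @return List with `record` (one-row tibble) and `events` (tibble).
#' @examples
#' fast_rat <- function(cued, ctx) list(choice = cued, latency_ms = 800)
#' run_trial("L", phase_config(1), fast_rat)$record
#' @export
run_trial <- function(cued_side, config, subject, t0 = 0,
                      trial = 1L, block = 1L,
                      is_hint = FALSE, hint_delay_ms = 0) {
  stopifnot(inherits(config, "phase_config"))
  res <- run_trial_core(as_side(cued_side), config, subject, t0 = t0,
                        trial = as.integer(trial), block = as.integer(block),
                        is_hint = is_hint, hint_delay_ms = hint_delay_ms)
  list(
    record = as_tibble(res$record),
    events = as_tibble(res$events)
  )
}

# ---- subjects ---------------------------------------------------------------

#' Coerce to a maze subject
#'
#' A maze subject is a list with callbacks `respond(cued_side, ctx)`,
#' `begin_block()` (called at each block start; history-dependent state such
#' as a lapse policy's memory resets here), `notify(choice, rewarded)` (reward
#' feedback after each trial) and `return_latency()` (the inter-trial interval
#' contributed by the animal returning to the start box). A bare function is
#' wrapped with no-op state callbacks and a fixed 3 s return latency.
#'
#' @param x A function or `maze_subject`.
#' @return A `maze_subject`.
#' @export
as_maze_subject <- function(x) {
  if (inherits(x, "maze_subject")) return(x)
  if (is.function(x)) {
    return(structure(
      list(
        respond = x,
        begin_block = function() invisible(NULL),
        notify = function(choice, rewarded) invisible(NULL),
        return_latency = function() 3000
      ),
      class = "maze_subject"
    ))
  }
  abort("`subject` must be a function or a maze_subject")
}

#' Run a block of trials
#'
#' Executes the trials of one schedule in order. The next trial's nose poke
#' occurs at the previous trial's end plus the subject's return latency
#' (animals can initiate a new trial immediately after the previous one ends,
#' so the inter-trial interval is set by how fast they return to the start
#' box). Hint trials are drawn per trial with the phase/day-dependent hint
#' fraction.
#'
#' @param schedule A `maze_schedule` (length must equal
#'   `config$trials_per_block`).
#' @param config A [phase_config()].
#' @param subject A callback function or [as_maze_subject()] object.
#' @param t_start Block start time, ms.
#' @param block 1-based block index.
#' @param day_in_phase Session number within the phase (drives the hint ramp).
#' @return List with `trials` (tibble of per-trial records), `events`
#'   (tibble) and `t_end`.
#' @examples
#' sched <- generate_sequence(10, seed = 1)
#' blk <- run_block(sched, phase_config(1),
#'                  function(cued, ctx) list(choice = cued, latency_ms = 500))
#' blk$trials
#' @export
run_block <- function(schedule, config, subject, t_start = 0, block = 1L,
                      day_in_phase = 1) {
  stopifnot(inherits(config, "phase_config"))
  cues <- if (inherits(schedule, "maze_schedule")) schedule$side else as_side(schedule)
  n <- length(cues)
  if (n != config$trials_per_block) {
    abort(sprintf("schedule has %d trials but phase %d blocks have %d",
                  n, config$phase, config$trials_per_block))
  }
  subject <- as_maze_subject(subject)
  hint_frac <- hint_fraction_for(config, day_in_phase)
  hint_delay <- hint_delay_for(config, day_in_phase)
  is_hint <- if (hint_frac > 0) runif(n) < hint_frac else rep(FALSE, n)
  subject$begin_block()
  t <- t_start
  recs <- vector("list", n)
  evs <- vector("list", n)
  for (i in seq_len(n)) {
    res <- run_trial_core(cues[i], config, subject$respond, t0 = t,
                          trial = i, block = as.integer(block),
                          is_hint = is_hint[i],
                          hint_delay_ms = if (is_hint[i]) hint_delay else 0)
    recs[[i]] <- res$record
    evs[[i]] <- res$events
    subject$notify(res$record$chosen_side, res$record$pellets > 0)
    t <- res$t_end + subject$return_latency()
  }
  trials <- as_tibble(purrr::list_transpose(recs, simplify = TRUE))
  trials$block <- as.integer(block)
  events <- as_tibble(purrr::map(
    setNames(names(evs[[1]]), names(evs[[1]])),
    function(f) unlist(purrr::map(evs, f), use.names = FALSE)
  ))
  list(trials = trials, events = events, t_end = t)
}

#' Run a full training session
#'
#' A session is `blocks_per_session` blocks (four by default). Each block gets
#' its own freshly generated constrained schedule; block seeds are derived
#' from the session seed and recorded, so any block can be replayed.
#'
#' @param phase Phase number 1-7, or a [phase_config()].
#' @param subject A callback function or [as_maze_subject()] object.
#' @param seed Integer session seed.
#' @param day Training day (global), stamped into the records.
#' @param day_in_phase Session number within the phase (hint ramp); defaults
#'   to `day`.
#' @param animal_id Identifier stamped into the records.
#' @param constraints [sequence_constraints()] for schedule generation.
#' @return A `maze_session`: list with `trials` tibble (columns `animal`,
#'   `day`, `phase`, `block`, `trial_index`, `cued_side`, `chosen_side`,
#'   `reaction_time_ms`, `pellets`, `outcome`, `is_hint`,
#'   `responded_pre_hint`, `t_start`, `t_end`), `events` tibble, `config`,
#'   `seed`, `block_seeds`.
#' @examples
#' s <- run_session(1, function(cued, ctx) list(choice = cued, latency_ms = 700),
#'                  seed = 42)
#' nrow(s$trials)
#' @export
run_session <- function(phase, subject, seed, day = 1, day_in_phase = day,
                        animal_id = "subject1",
                        constraints = sequence_constraints()) {
  config <- if (inherits(phase, "phase_config")) phase else phase_config(phase)
  if (missing(seed)) abort("`seed` is required")
  subject <- as_maze_subject(subject)
  n_blocks <- config$blocks_per_session
  out <- withr::with_seed(as.integer(seed), {
    block_seeds <- sample.int(2147483646L, n_blocks)
    t <- 0
    blocks <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      sched <- generate_sequence(config$trials_per_block, constraints,
                                 seed = block_seeds[b])
      blocks[[b]] <- run_block(sched, config, subject, t_start = t, block = b,
                               day_in_phase = day_in_phase)
      t <- blocks[[b]]$t_end + config$interblock_gap_ms
    }
    list(blocks = blocks, block_seeds = block_seeds)
  })
  trials <- dplyr::bind_rows(purrr::map(out$blocks, "trials"))
  trials <- dplyr::mutate(trials,
    animal = animal_id, day = as.integer(day), phase = config$phase,
    .before = 1
  )
  events <- dplyr::bind_rows(purrr::map(out$blocks, "events"))
  structure(
    list(
      trials = trials, events = events, config = config,
      seed = as.integer(seed), block_seeds = out$block_seeds,
      animal_id = animal_id, day = as.integer(day),
      day_in_phase = day_in_phase
    ),
    class = "maze_session"
  )
}

#' @export
print.maze_session <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<maze_session> %s day %d phase %d: %d trials, %.1f%% correct, %d timeout(s)\n",
    x$animal_id, x$day, x$config$phase, g$n_trials, g$pct_correct, g$n_timeouts
  ))
  invisible(x)
}

#' @rdname run_session
#' @param x A `maze_session`.
#' @param ... Unused.
#' @export
tidy.maze_session <- function(x, ...) x$trials

#' @rdname run_session
#' @export
glance.maze_session <- function(x, ...) {
  tibble(
    animal = x$animal_id, day = x$day, phase = x$config$phase,
    n_trials = nrow(x$trials),
    pct_correct = 100 * mean(x$trials$outcome == "CORRECT"),
    n_timeouts = sum(x$trials$outcome == "TIMEOUT"),
    n_hints = sum(x$trials$is_hint)
  )
}
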