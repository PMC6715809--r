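#' Virtual-rat parameters
#'
#' Parameters of the simulated animal used as a test fixture for the whole
#' pipeline. Per-trial behavior is layered: with probability `p_timeout` the
#' animal never reaches a reward area (trial times out); otherwise with
#' probability `p_strategy_lapse` it answers from a cue-ignoring lapse policy
#' (spontaneous alternation by default — the tendency the schedule
#' constraints exist to defeat); otherwise it follows the cue and is correct
#' with probability `p(day) = p_start + (p_asymptote - p_start) *
#' (1 - exp(-learning_rate * day))`, a saturating learning curve over global
#' training days. Latencies are log-normal — positive, right-skewed and
#' unimodal, matching observed reaction-time densities — parameterized by
#' their mode (reported summaries are modes) with a phase-specific mode that
#' grows with maze length, and a smaller log-scale spread on correct than on
#' incorrect trials (incorrect trials mix strategy-fast and distracted-slow
#' responses), truncated at the phase timeout.
#'
#' Defaults are calibrated so that, on the default 45-day training grid of
#' [training_schedule()], realized accuracy (timeouts scored incorrect,
#' hint trials excluded) averages about 59% over phase 1 and about 87% over
#' phase 7, and phase 5-7 modes lie in the 1-2 s range.
#'
#' @param p_start,p_asymptote Accuracy bounds of the learning curve
#'   (`0.5 <= p_start <= p_asymptote <= 1`).
#' @param learning_rate Learning-curve rate per training day.
#' @param rt_mode_ms Length-7 vector: latency mode (ms) per phase;
#'   must be non-decreasing over phases 5-7 as the maze grows.
#' @param rt_sigma_correct,rt_sigma_incorrect Log-scale spreads, with
#'   `rt_sigma_correct < rt_sigma_incorrect`.
#' @param p_timeout Per-trial probability of no response.
#' @param p_strategy_lapse Per-trial probability of answering from the lapse
#'   policy instead of the cue.
#' @param lapse_policy One of [policies()] except `RANDOM` is allowed too.
#' @param p_follow_hint Probability that a hint (dispensed before the animal
#'   responded) pulls the response to the cued side.
#' @param iti_mode_ms,iti_sigma Log-normal mode/spread of the return-to-start
#'   latency (inter-trial interval contribution).
#' @return A `subject_params` list.
#' @examples
#' subject_params()
#' @export
subject_params <- function(p_start = 0.50,
                           p_asymptote = 0.95,
                           learning_rate = 0.06,
                           rt_mode_ms = c(600, 700, 800, 900, 1200, 1500, 1800),
                           rt_sigma_correct = 0.25,
                           rt_sigma_incorrect = 0.45,
                           p_timeout = 0.02,
                           p_strategy_lapse = 0.05,
                           lapse_policy = "SPONT_ALTERNATE",
                           p_follow_hint = 0.85,
                           iti_mode_ms = 3000,
                           iti_sigma = 0.4) {
  stopifnot(
    p_start >= 0.5, p_start <= p_asymptote, p_asymptote <= 1,
    learning_rate >= 0,
    length(rt_mode_ms) == 7, all(rt_mode_ms > 0),
    all(diff(rt_mode_ms[5:7]) >= 0),
    rt_sigma_correct > 0, rt_sigma_incorrect > rt_sigma_correct,
    p_timeout >= 0, p_timeout <= 1,
    p_strategy_lapse >= 0, p_strategy_lapse + p_timeout <= 1,
    p_follow_hint >= 0, p_follow_hint <= 1
  )
  lapse_policy <- match.arg(lapse_policy, policies())
  structure(
    list(
      p_start = p_start, p_asymptote = p_asymptote,
      learning_rate = learning_rate, rt_mode_ms = rt_mode_ms,
      rt_sigma_correct = rt_sigma_correct,
      rt_sigma_incorrect = rt_sigma_incorrect,
      p_timeout = p_timeout, p_strategy_lapse = p_strategy_lapse,
      lapse_policy = lapse_policy, p_follow_hint = p_follow_hint,
      iti_mode_ms = iti_mode_ms, iti_sigma = iti_sigma
    ),
    class = "subject_params"
  )
}

#' @export
print.subject_params <- function(x, ...) {
  cat(sprintf(
    "<subject_params> p: %.2f -> %.2f (rate %.3f/day); sigma C/I %.2f/%.2f;\n  p_timeout %.2f, p_lapse %.2f (%s); RT modes %s ms\n",
    x$p_start, x$p_asymptote, x$learning_rate,
    x$rt_sigma_correct, x$rt_sigma_incorrect,
    x$p_timeout, x$p_strategy_lapse, x$lapse_policy,
    paste(x$rt_mode_ms, collapse = "/")
  ))
  invisible(x)
}

#' Learning-curve accuracy at a given training day
#'
#' `p(day) = p_start + (p_asymptote - p_start) * (1 - exp(-rate * day))`:
#' the probability that a cue-following (non-lapse, non-timeout) response is
#' correct.
#'
#' @param params A [subject_params()] object.
#' @param day Training day(s), numeric.
#' @return Numeric vector of probabilities.
#' @examples
#' learning_curve(subject_params(), c(1, 10, 40))
#' @export
learning_curve <- function(params, day) {
  stopifnot(inherits(params, "subject_params"))
  params$p_start + (params$p_asymptote - params$p_start) *
    (1 - exp(-params$learning_rate * day))
}

# log-normal draw parameterized by its mode: mode = exp(mu - sigma^2)
# => mu = log(mode) + sigma^2. Truncated at `upper` by inverse-CDF so the
# draw consumes exactly one uniform.
rlnorm_mode <- function(n, mode, sigma, upper = Inf) {
  mu <- log(mode) + sigma^2
  if (is.finite(upper)) {
    qlnorm(runif(n) * plnorm(upper, mu, sigma), mu, sigma)
  } else {
    qlnorm(runif(n), mu, sigma)
  }
}

#' Draw one virtual-rat response
#'
#' The per-trial generative model behind [virtual_subject()], exposed
#' directly for distribution-level checks. Draws outcome class
#' (timeout / lapse / cue-following), the chosen side and a latency.
#'
#' @param cued_side The cued side.
#' @param phase Phase 1-7 (selects latency mode and timeout).
#' @param day Global training day (learning curve input).
#' @param params A [subject_params()] object.
#' @param timeout_ms Truncation bound for the latency.
#' @param lapse_state Optional list with `last_choice`, `last_rewarded_side`
#'   feeding the lapse policy.
#' @return `NULL` (no response) or `list(choice, latency_ms, lapsed)`.
#' @examples
#' withr::with_seed(1, respond("L", 5, 30, subject_params()))
#' @export
respond <- function(cued_side, phase, day, params = subject_params(),
                    timeout_ms = phase_config(phase)$timeout_ms,
                    lapse_state = list()) {
  stopifnot(inherits(params, "subject_params"))
  cued_side <- as_side(cued_side)
  u <- runif(1)
  if (u < params$p_timeout) return(NULL)
  lapsed <- u < params$p_timeout + params$p_strategy_lapse
  if (lapsed) {
    choice <- policy_choice(params$lapse_policy,
                            last_choice = lapse_state$last_choice,
                            last_rewarded_side = lapse_state$last_rewarded_side)
  } else {
    p <- learning_curve(params, day)
    choice <- if (runif(1) < p) cued_side else side_complement(cued_side)
  }
  sigma <- if (choice == cued_side) params$rt_sigma_correct else params$rt_sigma_incorrect
  latency <- rlnorm_mode(1, params$rt_mode_ms[phase], sigma, upper = timeout_ms)
  list(choice = choice, latency_ms = latency, lapsed = lapsed)
}

#' Create a virtual rat
#'
#' Wraps the generative model of [respond()] into a stateful
#' [as_maze_subject()] object usable by [run_block()]/[run_session()]: it
#' tracks its own last choice and last rewarded side within a block (for the
#' lapse policy), resets that history at block starts, follows hints with
#' probability `p_follow_hint` when it had not yet responded at hint time,
#' and supplies log-normal return-to-start latencies.
#'
#' @param params A [subject_params()] object.
#' @param day Global training day the subject is simulated at (can be changed
#'   between sessions via the `set_day` callback).
#' @return A `maze_subject` with an extra `set_day(day)` callback.
#' @examples
#' rat <- virtual_subject(subject_params(), day = 20)
#' s <- run_session(5, rat, seed = 4)
#' glance(s)
#' @export
virtual_subject <- function(params = subject_params(), day = 1) {
  stopifnot(inherits(params, "subject_params"))
  state <- new.env(parent = emptyenv())
  state$day <- day
  state$last_choice <- NULL
  state$last_rewarded <- NULL
  structure(
    list(
      respond = function(cued_side, ctx) {
        r <- respond(cued_side, ctx$phase, state$day, params,
                     timeout_ms = ctx$timeout_ms,
                     lapse_state = list(last_choice = state$last_choice,
                                        last_rewarded_side = state$last_rewarded))
        if (is.null(r)) return(NULL)
        if (isTRUE(ctx$is_hint) && r$latency_ms > ctx$hint_delay_ms &&
            r$choice != cued_side && runif(1) < params$p_follow_hint) {
          r$choice <- cued_side   # the hint pellet draws the animal over
        }
        list(choice = r$choice, latency_ms = r$latency_ms)
      },
      begin_block = function() {
        state$last_choice <- NULL
        state$last_rewarded <- NULL
        invisible(NULL)
      },
      notify = function(choice, rewarded) {
        if (!is.na(choice)) {
          state$last_choice <- choice
          if (isTRUE(rewarded)) state$last_rewarded <- choice
        }
        invisible(NULL)
      },
      return_latency = function() {
        rlnorm_mode(1, params$iti_mode_ms, params$iti_sigma)
      },
      set_day = function(day) {
        state$day <- day
        invisible(NULL)
      }
    ),
    class = "maze_subject"
  )
}

#' Default training calendar
#'
#' Maps global training days to phases. The default 45-day grid spends the
#' most sessions on the slow early cue-training and on the final full-size
#' task: 6/5/5/5/6/8/10 days for phases 1-7.
#'
#' @param days_per_phase Length-7 integer vector of sessions per phase.
#' @return A tibble with columns `day`, `phase`, `day_in_phase`.
#' @examples
#' dplyr::count(training_schedule(), phase)
#' @export
training_schedule <- function(days_per_phase = c(6L, 5L, 5L, 5L, 6L, 8L, 10L)) {
  stopifnot(length(days_per_phase) == 7, all(days_per_phase >= 1))
  phase <- rep(1:7, times = days_per_phase)
  tibble(
    day = seq_along(phase),
    phase = as.integer(phase),
    day_in_phase = unlist(purrr::map(days_per_phase, seq_len), use.names = FALSE)
  )
}

#' Simulate a full training study
#'
#' Runs virtual rats through the complete multi-phase training calendar, one
#' session (four blocks) per animal-day, and returns the pooled trial
#' records — the package's end-to-end synthetic data generator.
#'
#' @param params A [subject_params()] object (shared by all animals).
#' @param schedule A [training_schedule()] tibble.
#' @param n_animals Number of virtual rats.
#' @param seed Master seed; all session seeds derive from it.
#' @param constraints [sequence_constraints()] used for every block schedule.
#' @param keep_events Also return the concatenated event tibble (larger).
#' @return A tibble of trial records across animals and days (see
#'   [run_session()]), with attribute `"events"` when `keep_events = TRUE`.
#' @examples
#' trials <- simulate_training(n_animals = 1,
#'                             schedule = training_schedule()[1:2, ],
#'                             seed = 11)
#' dplyr::count(trials, outcome)
#' @export
simulate_training <- function(params = subject_params(),
                              schedule = training_schedule(),
                              n_animals = 4,
                              seed,
                              constraints = sequence_constraints(),
                              keep_events = FALSE) {
  if (missing(seed)) abort("`seed` is required")
  stopifnot(all(c("day", "phase", "day_in_phase") %in% names(schedule)))
  session_seeds <- withr::with_seed(
    as.integer(seed),
    matrix(sample.int(2147483646L, n_animals * nrow(schedule)),
           nrow = n_animals)
  )
  res <- purrr::map(seq_len(n_animals), function(a) {
    rat <- virtual_subject(params)
    purrr::map(seq_len(nrow(schedule)), function(i) {
      rat$set_day(schedule$day[i])
      run_session(
        phase_config(schedule$phase[i]), rat,
        seed = session_seeds[a, i],
        day = schedule$day[i], day_in_phase = schedule$day_in_phase[i],
        animal_id = sprintf("rat%02d", a),
        constraints = constraints
      )
    })
  })
  sessions <- purrr::flatten(res)
  trials <- dplyr::bind_rows(purrr::map(sessions, "trials"))
  if (keep_events) {
    events <- dplyr::bind_rows(purrr::map(sessions, function(s) {
      dplyr::mutate(s$events, animal = s$animal_id, day = s$day, .before = 1)
    }))
    attr(trials, "events") <- events
  }
  trials
}
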