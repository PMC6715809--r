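#' Null response strategies
#'
#' The six cue-ignoring policies used to certify the sequence generator and to
#' score animals' responses for strategy compliance: constant side biases
#' (`ALWAYS_LEFT`, `ALWAYS_RIGHT`), `WIN_STAY` (return to the side rewarded
#' most recently), `WIN_SHIFT` (go opposite the side rewarded most recently),
#' `SPONT_ALTERNATE` (go opposite one's own previous choice — the rodents'
#' innate alternation tendency), and `RANDOM`.
#'
#' @return Character vector of policy names.
#' @examples
#' policies()
#' @export
policies <- function() {
  c("ALWAYS_LEFT", "ALWAYS_RIGHT", "WIN_STAY", "WIN_SHIFT",
    "SPONT_ALTERNATE", "RANDOM")
}

random_side <- function() as_side(sample(c(0L, 1L), 1L))

#' Choice of a null policy given its state
#'
#' Returns the side a policy would choose given the history it tracks:
#' `last_choice` (the previous response) and `last_rewarded_side` (the side of
#' the most recent rewarded trial). `WIN_STAY` returns `last_rewarded_side`
#' and `WIN_SHIFT` its complement; while no reward has occurred yet they fall
#' back to repeating / complementing `last_choice`. `SPONT_ALTERNATE` returns
#' the complement of `last_choice`. On the very first trial (no history at
#' all) the history-dependent policies choose uniformly at random, so calls
#' may advance the RNG.
#'
#' @param policy One of [policies()].
#' @param last_choice,last_rewarded_side Sides (`"L"`/`"R"`) or `NULL`/`NA`
#'   when that part of the history does not exist yet.
#' @return A side, `"L"` or `"R"`.
#' @examples
#' policy_choice("WIN_STAY", last_rewarded_side = "L")
#' policy_choice("WIN_SHIFT", last_rewarded_side = "L")
#' policy_choice("SPONT_ALTERNATE", last_choice = "R")
#' @export
policy_choice <- function(policy, last_choice = NULL,
                          last_rewarded_side = NULL) {
  policy <- match.arg(policy, policies())
  lc <- if (is.null(last_choice) || is.na(last_choice)) NULL else as_side(last_choice)
  lr <- if (is.null(last_rewarded_side) || is.na(last_rewarded_side)) NULL else as_side(last_rewarded_side)
  switch(policy,
    ALWAYS_LEFT = "L",
    ALWAYS_RIGHT = "R",
    RANDOM = random_side(),
    WIN_STAY = if (!is.null(lr)) lr else if (!is.null(lc)) lc else random_side(),
    WIN_SHIFT = if (!is.null(lr)) side_complement(lr)
                else if (!is.null(lc)) side_complement(lc) else random_side(),
    SPONT_ALTERNATE = if (!is.null(lc)) side_complement(lc) else random_side()
  )
}

#' Simulate a null policy against a block schedule
#'
#' Runs a policy trial-by-trial against the scheduled cue sequence. The policy
#' never sees the cue: a choice is correct (and rewarded) iff it equals the
#' scheduled side, and only reward feedback updates the policy state. Given
#' the first-trial choice, the non-`RANDOM` policies are deterministic.
#'
#' Two conventions exist for what win-stay/win-shift do after an unrewarded
#' trial, and they matter: under `loss_rule = "carry"` (the default) the
#' policies keep acting on the most recent rewarded side, which makes
#' win-stay collapse into a side bias from its first reward onward (it only
#' ever re-experiences reward at the side it already occupies); under
#' `loss_rule = "react"` they respond to the previous trial's own outcome
#' (win-stay/lose-shift and win-shift/lose-stay, the classic pair), in which
#' case the two policies' choices are exactly complementary from trial 2
#' onward when started from the same first choice.
#'
#' @param policy One of [policies()].
#' @param schedule A `maze_schedule`, or a vector of sides.
#' @param seed Optional integer seed for the policy's random draws (first
#'   trial of history-dependent policies; every trial of `RANDOM`).
#' @param first_choice Optional side to force as the first-trial choice.
#' @param loss_rule `"carry"` (act on the most recent rewarded side, carried
#'   across losses) or `"react"` (respond to the previous trial's outcome).
#'   Only affects `WIN_STAY`/`WIN_SHIFT`.
#' @return A `strategy_result`: list with `policy`, `percent_correct` (0-100)
#'   and `trials`, a tibble of per-trial cue, choice, correctness and reward.
#' @examples
#' simulate_strategy("WIN_SHIFT", c("L", "R", "R", "L"), first_choice = "L")
#' @export
simulate_strategy <- function(policy, schedule, seed = NULL,
                              first_choice = NULL,
                              loss_rule = c("carry", "react")) {
  policy <- match.arg(policy, policies())
  loss_rule <- match.arg(loss_rule)
  cues <- if (inherits(schedule, "maze_schedule")) schedule$side else as_side(schedule)
  n <- length(cues)
  if (n == 0) abort("empty schedule")
  reactive <- loss_rule == "react" && policy %in% c("WIN_STAY", "WIN_SHIFT")
  run <- function() {
    lc <- NULL
    lr <- NULL
    last_win <- NA
    choices <- character(n)
    for (i in seq_len(n)) {
      ch <- if (i == 1 && !is.null(first_choice)) {
        as_side(first_choice)
      } else if (reactive && i > 1) {
        stay <- if (policy == "WIN_STAY") last_win else !last_win
        if (stay) lc else side_complement(lc)
      } else {
        policy_choice(policy, last_choice = lc, last_rewarded_side = lr)
      }
      choices[i] <- ch
      last_win <- ch == cues[i]
      if (last_win) lr <- ch
      lc <- ch
    }
    choices
  }
  choices <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  correct <- choices == cues
  structure(
    list(
      policy = policy,
      percent_correct = 100 * mean(correct),
      trials = tibble(
        trial_index = seq_len(n) - 1L,
        cued_side = cues,
        choice = choices,
        correct = correct,
        rewarded = correct
      )
    ),
    class = "strategy_result"
  )
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf(
    "<strategy_result> %s: %.1f%% correct over %d trials\n",
    x$policy, x$percent_correct, nrow(x$trials)
  ))
  invisible(x)
}

#' @rdname simulate_strategy
#' @param x A `strategy_result`.
#' @param ... Unused.
#' @export
tidy.strategy_result <- function(x, ...) x$trials

#' @rdname simulate_strategy
#' @export
glance.strategy_result <- function(x, ...) {
  tibble(policy = x$policy, percent_correct = x$percent_correct,
         n_trials = nrow(x$trials))
}

# ---- vectorised policy simulation over a sequence matrix --------------------
#
# `seqs` is an m x n 0/1 matrix of cue sequences (0 = L). Returns the m-vector
# of per-sequence percent correct. State is carried column-wise so all m
# sequences advance in lock-step; agrees row-for-row with simulate_strategy()
# (property-tested).
simulate_policy_batch <- function(policy, seqs, first_choice = NULL) {
  policy <- match.arg(policy, policies())
  m <- nrow(seqs)
  n <- ncol(seqs)
  if (policy %in% c("ALWAYS_LEFT", "ALWAYS_RIGHT")) {
    const <- if (policy == "ALWAYS_LEFT") 0L else 1L
    hits <- rowSums(seqs == const)
    if (!is.null(first_choice)) {   # a forced first trial overrides the bias
      hits <- hits - (seqs[, 1] == const) + (seqs[, 1] == as.integer(first_choice))
    }
    return(100 * hits / n)
  }
  if (policy == "RANDOM") {
    ch <- matrix(sample(c(0L, 1L), m * n, replace = TRUE), m, n)
    return(100 * rowMeans(ch == seqs))
  }
  correct_n <- numeric(m)
  lc <- if (is.null(first_choice)) {
    sample(c(0L, 1L), m, replace = TRUE)       # first-trial choice
  } else {
    rep_len(as.integer(first_choice), m)
  }
  lr <- rep(NA_integer_, m)
  for (j in seq_len(n)) {
    ch <- if (j == 1) {
      lc
    } else {
      switch(policy,
        WIN_STAY = ifelse(is.na(lr), lc, lr),
        WIN_SHIFT = 1L - ifelse(is.na(lr), lc, lr),
        SPONT_ALTERNATE = 1L - lc
      )
    }
    hit <- ch == seqs[, j]
    correct_n <- correct_n + hit
    lr[hit] <- ch[hit]
    lc <- ch
  }
  100 * correct_n / n
}

#' Certify the sequence generator against null strategies
#'
#' Simulates each null policy on freshly generated schedules at each session
#' length used in training and averages the percent of rewarded trials. The
#' generator is certified when no policy can, on average, score above the
#' ceiling (60% by design): an animal gets no mileage from side biases,
#' win-stay/win-shift or spontaneous alternation and must attend to the cue.
#'
#' @param constraints A [sequence_constraints()] object.
#' @param session_lengths Trials per block to audit (defaults to the four
#'   block lengths used across the seven training phases).
#' @param n_sequences Schedules generated per session length.
#' @param seed Integer seed (the audit is deterministic given the seed).
#' @param ceiling Certification ceiling in percent.
#' @param audit_policies Policies to simulate; defaults to all of [policies()].
#' @return A `strategy_audit`: list with `results` (tibble `policy`,
#'   `session_length`, `mean_pct_correct`), `certified` flag, `max_mean_pct`,
#'   `ceiling`.
#' @examples
#' aud <- audit_generator(n_sequences = 300, seed = 5)
#' glance(aud)
#' @export
audit_generator <- function(constraints = sequence_constraints(),
                            session_lengths = c(10, 15, 20, 25),
                            n_sequences = 10000,
                            seed,
                            ceiling = 60,
                            audit_policies = policies()) {
  stopifnot(length(session_lengths) >= 1, n_sequences >= 1)
  if (missing(seed)) abort("`seed` is required")
  audit_policies <- match.arg(audit_policies, policies(), several.ok = TRUE)
  results <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(session_lengths, function(len) {
      seqs <- draw_accepted_batch(n_sequences, len, constraints)
      purrr::map_dfr(audit_policies, function(pol) {
        tibble(
          policy = pol,
          session_length = as.integer(len),
          mean_pct_correct = mean(simulate_policy_batch(pol, seqs))
        )
      })
    })
  })
  max_mean <- max(results$mean_pct_correct)
  structure(
    list(
      results = results,
      certified = max_mean <= ceiling,
      max_mean_pct = max_mean,
      ceiling = ceiling,
      n_sequences = as.integer(n_sequences),
      constraints = constraints,
      seed = as.integer(seed)
    ),
    class = "strategy_audit"
  )
}

#' @export
print.strategy_audit <- function(x, ...) {
  cat(sprintf(
    "<strategy_audit> %s (max mean %.1f%%, ceiling %.0f%%, %d sequences/length)\n",
    if (x$certified) "CERTIFIED" else "NOT certified",
    x$max_mean_pct, x$ceiling, x$n_sequences
  ))
  wide <- tidyr::pivot_wider(x$results, names_from = "session_length",
                             values_from = "mean_pct_correct")
  print(wide)
  invisible(x)
}

#' @rdname audit_generator
#' @param x A `strategy_audit`.
#' @param ... Unused.
#' @export
tidy.strategy_audit <- function(x, ...) x$results

#' @rdname audit_generator
#' @export
glance.strategy_audit <- function(x, ...) {
  tibble(
    certified = x$certified, max_mean_pct = x$max_mean_pct,
    ceiling = x$ceiling, n_sequences = x$n_sequences,
    n_policies = length(unique(x$results$policy)),
    n_lengths = length(unique(x$results$session_length))
  )
}

#' Strategy compliance of a response stream
#'
#' Scores how well a block of observed responses matches the trial-by-trial
#' predictions of a null policy. The policy state is seeded from the response
#' to the first cue in the block (and its reward outcome); each later trial is
#' predicted from the *actual* response/reward history up to that point, and
#' compliance is the percent of predicted responses equal to actual responses
#' over trials 2..n.
#'
#' @param responses Observed choices, sides (`"L"`/`"R"`), length >= 2.
#' @param outcomes Logical reward flags, same length as `responses`.
#' @param policy One of [policies()] except `RANDOM` (whose predictions are
#'   undefined trial-by-trial).
#' @return Percent compliance in \[0, 100\].
#' @examples
#' r <- c("L", "R", "L", "R", "L")
#' compliance(r, rep(TRUE, 5), "SPONT_ALTERNATE")
#' @export
compliance <- function(responses, outcomes, policy) {
  policy <- match.arg(policy, setdiff(policies(), "RANDOM"))
  responses <- as_side(responses)
  if (length(responses) != length(outcomes)) {
    abort("`responses` and `outcomes` must have the same length")
  }
  n <- length(responses)
  if (n < 2) abort("need at least 2 trials to score compliance")
  outcomes <- as.logical(outcomes)
  match_n <- 0L
  lc <- responses[1]
  lr <- if (isTRUE(outcomes[1])) responses[1] else NULL
  for (i in 2:n) {
    pred <- policy_choice(policy, last_choice = lc, last_rewarded_side = lr)
    if (pred == responses[i]) match_n <- match_n + 1L
    if (isTRUE(outcomes[i])) lr <- responses[i]
    lc <- responses[i]
  }
  100 * match_n / (n - 1)
}
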