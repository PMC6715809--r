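#' Constraints on a block's cue sequence
#'
#' A block's sequence of cued sides is drawn i.i.d. uniform and accepted only
#' if it satisfies three constraints designed to defeat non-task response
#' strategies: no side may repeat for more than `max_run_length` consecutive
#' trials (prevents side biases from paying off), the fraction of side-switch
#' transitions must lie inside `alternation_band` (the default band is centred
#' on a 40/60 switch/stay ratio, chosen to actively discourage the rodents'
#' innate alternation tendency), and the left/right counts may differ by at
#' most `max_side_imbalance` (counterbalancing).
#'
#' @param max_run_length Longest permitted run of identical sides (trials).
#' @param alternation_band Closed interval in \[0, 1\]: admissible fraction of
#'   transitions that switch side.
#' @param max_side_imbalance Maximum permitted `|#L - #R|` (trials).
#' @param max_rejections Upper bound on candidate draws before
#'   [generate_sequence()] gives up (a guard against infeasible constraints).
#' @return An object of class `sequence_constraints`.
#' @examples
#' sequence_constraints()
#' sequence_constraints(alternation_band = c(0, 1), max_side_imbalance = 25)
#' @export
sequence_constraints <- function(max_run_length = 3,
                                 alternation_band = c(0.35, 0.45),
                                 max_side_imbalance = 1,
                                 max_rejections = 1e5) {
  stopifnot(
    length(max_run_length) == 1, max_run_length >= 1,
    length(alternation_band) == 2,
    alternation_band[1] >= 0, alternation_band[2] <= 1,
    alternation_band[1] <= alternation_band[2],
    length(max_side_imbalance) == 1, max_side_imbalance >= 0,
    max_rejections >= 1
  )
  structure(
    list(
      max_run_length = as.integer(max_run_length),
      alternation_band = as.numeric(alternation_band),
      max_side_imbalance = as.integer(max_side_imbalance),
      max_rejections = as.integer(max_rejections)
    ),
    class = "sequence_constraints"
  )
}

#' @export
print.sequence_constraints <- function(x, ...) {
  cat("<sequence_constraints>\n")
  cat("  max run length     :", x$max_run_length, "\n")
  cat(sprintf(
    "  alternation band   : [%.2f, %.2f]\n",
    x$alternation_band[1], x$alternation_band[2]
  ))
  cat("  max side imbalance :", x$max_side_imbalance, "\n")
  cat("  max rejections     :", x$max_rejections, "\n")
  invisible(x)
}

#' Descriptive statistics of a cue sequence
#'
#' Computes the measures used to audit the sequence generator: side frequency,
#' alternation fraction (proportion of the `n - 1` transitions whose side
#' differs from the previous trial), the longest same-side run, and the counts
#' of left-to-right and right-to-left transitions. For a single-trial sequence
#' the transition-based statistics are `NA`.
#'
#' @param sides Sides as `"L"`/`"R"` (or 0/1), length at least 1.
#' @return A one-row tibble with columns `n`, `frac_left`, `alternation_frac`,
#'   `max_run`, `n_lr`, `n_rl`.
#' @examples
#' sequence_stats(c("L", "L", "R", "L"))
#' @export
sequence_stats <- function(sides) {
  s <- side_to_int(as_side(sides))
  if (length(s) == 0) abort("empty sequence")
  n <- length(s)
  if (n == 1) {
    return(tibble(
      n = 1L, frac_left = as.numeric(s == 0), alternation_frac = NA_real_,
      max_run = 1L, n_lr = NA_integer_, n_rl = NA_integer_
    ))
  }
  d <- diff(s)
  tibble(
    n = n,
    frac_left = mean(s == 0),
    alternation_frac = mean(d != 0),
    max_run = max(rle(s)$lengths),
    n_lr = sum(d == 1L),
    n_rl = sum(d == -1L)
  )
}

# cheap scalar validator on 0/1 integer vectors (hot path of the
# rejection sampler; no side conversion, no tibble)
seq_ok_int <- function(s, constraints) {
  n <- length(s)
  if (abs(2L * sum(s) - n) > constraints$max_side_imbalance) return(FALSE)
  if (n > 1L) {
    d <- s[-1L] != s[-n]
    af <- mean(d)
    if (af < constraints$alternation_band[1] ||
        af > constraints$alternation_band[2]) {
      return(FALSE)
    }
    if (max(rle(s)$lengths) > constraints$max_run_length) return(FALSE)
  }
  TRUE
}

#' Validate a cue sequence against constraints
#'
#' A sequence fails if its longest run exceeds `max_run_length`, if its
#' alternation fraction falls outside `alternation_band` (not checked for
#' single-trial sequences, which have no transitions), or if its side
#' imbalance exceeds `max_side_imbalance`.
#'
#' @param sides Sides as `"L"`/`"R"` (or 0/1), non-empty.
#' @param constraints A [sequence_constraints()] object.
#' @return A list with elements `pass` (logical) and `stats` (the
#'   [sequence_stats()] tibble).
#' @examples
#' validate_sequence(c("L", "L", "L", "L", "R"), sequence_constraints())$pass
#' @export
validate_sequence <- function(sides, constraints = sequence_constraints()) {
  stopifnot(inherits(constraints, "sequence_constraints"))
  s <- side_to_int(as_side(sides))
  if (length(s) == 0) abort("empty sequence")
  if (anyNA(s)) abort("sequence contains missing sides")
  list(pass = seq_ok_int(s, constraints), stats = sequence_stats(sides))
}

#' Generate a constrained pseudorandom block schedule
#'
#' Draws a sequence of i.i.d. uniform sides for one block and rejects the
#' whole sequence if it violates any constraint, redrawing until a sequence is
#' accepted (rejection sampling; whole-sequence rejection avoids the biased
#' transition statistics that local repair would introduce). The RNG is seeded
#' per block and the seed is stored in the result so any schedule can be
#' replayed for audit.
#'
#' @param n_trials Number of trials in the block.
#' @param constraints A [sequence_constraints()] object.
#' @param seed Integer seed for this block's generator.
#' @return A `maze_schedule`: a tibble with columns `trial_index` (0-based)
#'   and `side`, carrying attributes `seed`, `constraints`, `n_attempts` and
#'   `stats`.
#' @examples
#' sched <- generate_sequence(25, seed = 7)
#' sched
#' attr(sched, "stats")
#' @export
generate_sequence <- function(n_trials,
                              constraints = sequence_constraints(),
                              seed) {
  stopifnot(n_trials >= 1, inherits(constraints, "sequence_constraints"))
  if (missing(seed)) abort("`seed` is required: schedules must be replayable")
  s <- NULL
  attempts <- 0L
  withr::with_seed(as.integer(seed), {
    repeat {
      attempts <- attempts + 1L
      if (attempts > constraints$max_rejections) {
        abort(paste0(
          "no sequence accepted after ", constraints$max_rejections,
          " draws; constraints are likely infeasible for n_trials = ", n_trials
        ))
      }
      cand <- sample(c(0L, 1L), n_trials, replace = TRUE)
      if (seq_ok_int(cand, constraints)) {
        s <- cand
        break
      }
    }
  })
  sides <- as_side(s)
  out <- tibble(trial_index = seq_len(n_trials) - 1L, side = sides)
  structure(
    out,
    class = c("maze_schedule", class(out)),
    seed = as.integer(seed),
    constraints = constraints,
    n_attempts = attempts,
    stats = sequence_stats(sides)
  )
}

#' @export
print.maze_schedule <- function(x, ...) {
  st <- attr(x, "stats")
  cat(sprintf(
    "<maze_schedule> %d trials (seed %d, %d draw%s)\n",
    nrow(x), attr(x, "seed"), attr(x, "n_attempts"),
    if (attr(x, "n_attempts") == 1) "" else "s"
  ))
  cat(" ", paste(x$side, collapse = " "), "\n")
  cat(sprintf(
    "  frac left %.2f | alternation %.2f | max run %d\n",
    st$frac_left, st$alternation_frac, st$max_run
  ))
  invisible(x)
}

# ---- vectorised batch rejection sampler -------------------------------------

# Per-row stats of an m x n 0/1 matrix, without per-row R calls.
batch_seq_stats <- function(mat) {
  m <- nrow(mat)
  n <- ncol(mat)
  if (n == 1) {
    return(tibble(
      n = rep(1L, m), frac_left = as.numeric(mat[, 1] == 0),
      alternation_frac = NA_real_, max_run = rep(1L, m),
      n_lr = NA_integer_, n_rl = NA_integer_
    ))
  }
  d <- mat[, -1, drop = FALSE] - mat[, -n, drop = FALSE]
  switches <- rowSums(d != 0)
  run <- rep(1L, m)
  max_run <- rep(1L, m)
  for (j in 2:n) {
    run <- run * (mat[, j] == mat[, j - 1]) + 1L
    max_run <- pmax(max_run, run)
  }
  tibble(
    n = rep(n, m),
    frac_left = rowMeans(mat == 0),
    alternation_frac = switches / (n - 1),
    max_run = as.integer(max_run),
    n_lr = as.integer(rowSums(d == 1)),
    n_rl = as.integer(rowSums(d == -1))
  )
}

batch_accept_mask <- function(mat, constraints) {
  n <- ncol(mat)
  imbalance <- abs(2 * rowSums(mat) - n)
  ok <- imbalance <= constraints$max_side_imbalance
  if (n > 1) {
    st <- batch_seq_stats(mat)
    ok <- ok &
      st$alternation_frac >= constraints$alternation_band[1] &
      st$alternation_frac <= constraints$alternation_band[2] &
      st$max_run <= constraints$max_run_length
  }
  ok
}

# Chunked rejection: candidates drawn i.i.d. uniform in fixed-size chunks and
# filtered in order — distributionally identical to one-at-a-time rejection.
draw_accepted_rejection <- function(m, n, constraints, chunk = 16384L) {
  got <- 0L
  drawn <- 0L
  pieces <- list()
  budget <- max(constraints$max_rejections, m * 64) * max(1, m / 100)
  while (got < m) {
    if (drawn > budget) {
      abort("batch sampler exceeded its draw budget; constraints likely infeasible")
    }
    cand <- matrix(sample(c(0L, 1L), chunk * n, replace = TRUE), chunk, n)
    drawn <- drawn + chunk
    keep <- batch_accept_mask(cand, constraints)
    if (any(keep)) {
      pieces[[length(pieces) + 1L]] <- cand[keep, , drop = FALSE]
      got <- got + sum(keep)
    }
  }
  out <- do.call(rbind, pieces)[seq_len(m), , drop = FALSE]
  attr(out, "n_candidates") <- drawn
  out
}

# ---- exact sampler over the acceptance set ----------------------------------
#
# Rejection sampling of i.i.d. uniform sides conditions on acceptance, i.e. it
# draws uniformly from the set of valid sequences. For audits that need tens
# of thousands of accepted sequences at acceptance rates as low as ~3e-4 we
# sample that same uniform distribution directly: a backward dynamic program
# counts, for every state (trial i, current side, current run length, switch
# count, left count), the number of valid completions, and sequences are drawn
# forward with transition probabilities proportional to those counts. The
# equivalence with generate_sequence() is property-tested against exhaustive
# enumeration at small n.

dp_state_size <- function(n, constraints) {
  mr <- min(constraints$max_run_length, n)
  as.numeric(n) * 2 * mr * n * (n + 1)
}

dp_count_valid <- function(n, constraints) {
  mr <- as.integer(min(constraints$max_run_length, n))
  ns <- as.integer(n)              # switch counts 0..n-1
  # F[i, side+1, r, s+1, l+1]: number of valid completions of trials i+1..n
  # given that trial i ended with `side`, a same-side run of length r,
  # s switches and l left trials so far.
  F <- array(0, dim = c(n, 2L, mr, ns, n + 1L))
  lo <- constraints$alternation_band[1]
  hi <- constraints$alternation_band[2]
  imb <- constraints$max_side_imbalance
  # terminal layer: states at i = n that satisfy the global constraints
  for (side in 0:1) for (r in seq_len(mr)) for (s in seq_len(ns) - 1L) {
    if (n > 1) {
      af <- s / (n - 1)
      if (af < lo || af > hi) next
    }
    for (l in 0:n) {
      if (abs(2L * l - n) <= imb) F[n, side + 1L, r, s + 1L, l + 1L] <- 1
    }
  }
  if (n == 1) return(F)
  for (i in (n - 1L):1L) {
    for (side in 0:1) for (r in seq_len(mr)) {
      s_max <- min(i - 1L, ns - 1L)
      for (s in 0:s_max) for (l in 0:i) {
        stay <- if (r < mr) {
          F[i + 1L, side + 1L, r + 1L, s + 1L, l + (side == 0L) + 1L]
        } else 0
        other <- 1L - side
        sw <- if (s + 1L <= ns - 1L) {
          F[i + 1L, other + 1L, 1L, s + 2L, l + (other == 0L) + 1L]
        } else 0
        F[i, side + 1L, r, s + 1L, l + 1L] <- stay + sw
      }
    }
  }
  F
}

# Draw m sequences uniformly from the acceptance set using the current RNG
# stream, walking the DP counts forward (vectorised across sequences).
draw_accepted_dp <- function(m, n, constraints, F = NULL) {
  if (is.null(F)) F <- dp_count_valid(n, constraints)
  wL <- F[1, 1, 1, 1, 2]   # first trial L: run 1, 0 switches, 1 left
  wR <- F[1, 2, 1, 1, 1]
  if (wL + wR == 0) {
    abort(sprintf("constraints admit no valid sequence of %d trials", n))
  }
  out <- matrix(0L, m, n)
  side <- as.integer(runif(m) < wR / (wL + wR))
  out[, 1] <- side
  r <- rep(1L, m)
  s <- rep(0L, m)
  l <- as.integer(side == 0L)
  mr <- as.integer(min(constraints$max_run_length, n))
  if (n > 1) {
    for (i in 1:(n - 1L)) {
      stay_w <- numeric(m)
      can_stay <- r < mr
      if (any(can_stay)) {
        idx <- cbind(i + 1L, side[can_stay] + 1L, r[can_stay] + 1L,
                     s[can_stay] + 1L, l[can_stay] + (side[can_stay] == 0L) + 1L)
        stay_w[can_stay] <- F[idx]
      }
      other <- 1L - side
      idx_sw <- cbind(i + 1L, other + 1L, 1L, s + 2L,
                      l + (other == 0L) + 1L)
      sw_w <- F[idx_sw]
      switch_now <- runif(m) * (stay_w + sw_w) >= stay_w
      side <- ifelse(switch_now, other, side)
      r <- ifelse(switch_now, 1L, r + 1L)
      s <- s + as.integer(switch_now)
      l <- l + as.integer(side == 0L)
      out[, i + 1L] <- side
    }
  }
  # the DP gives the exact acceptance probability of the rejection scheme;
  # report the equivalent candidate count so acceptance rates stay comparable
  attr(out, "n_candidates") <- m * 2^n / (wL + wR)
  attr(out, "sampler") <- "dp"
  out
}

# dispatcher: exact DP sampling when the state table is small enough,
# chunked rejection otherwise. Both draw from the same distribution.
draw_accepted_batch <- function(m, n, constraints) {
  if (dp_state_size(n, constraints) <= 5e6) {
    draw_accepted_dp(m, n, constraints)
  } else {
    draw_accepted_rejection(m, n, constraints)
  }
}

#' Monte-Carlo audit of the sequence generator
#'
#' Regenerates block schedules many times (the design-time audit used ten
#' thousand draws) and tabulates, per accepted sequence, the side frequency,
#' alternation fraction, longest run and directional transition counts, plus
#' their aggregates. Any residual pattern in these aggregates would signal a
#' bias an animal could exploit.
#'
#' @param n_sequences Number of accepted sequences to generate.
#' @param n_trials Trials per sequence.
#' @param constraints A [sequence_constraints()] object.
#' @param seed Integer seed; the audit is deterministic given the seed.
#' @param keep_sequences Keep the accepted 0/1 sequence matrix in the result
#'   (used by the strategy simulations); default `TRUE`.
#' @return A `maze_sequence_audit`: list with `stats` (tibble, one row per
#'   sequence), `summary` (per-measure mean/min/max), `sequences` (0/1 matrix
#'   or `NULL`), `acceptance_rate`, `constraints`, `seed`.
#' @examples
#' aud <- monte_carlo_audit(500, 25, seed = 1)
#' glance(aud)
#' @export
monte_carlo_audit <- function(n_sequences, n_trials,
                              constraints = sequence_constraints(),
                              seed,
                              keep_sequences = TRUE) {
  stopifnot(n_sequences >= 1, n_trials >= 1)
  if (missing(seed)) abort("`seed` is required")
  mat <- withr::with_seed(
    as.integer(seed),
    draw_accepted_batch(n_sequences, n_trials, constraints)
  )
  stats <- batch_seq_stats(mat)
  measures <- c("frac_left", "alternation_frac", "max_run")
  summary <- purrr::map_dfr(measures, function(mm) {
    v <- stats[[mm]]
    tibble(
      measure = mm, mean = mean(v, na.rm = TRUE),
      min = suppressWarnings(min(v, na.rm = TRUE)),
      max = suppressWarnings(max(v, na.rm = TRUE))
    )
  })
  structure(
    list(
      stats = dplyr::mutate(stats, sequence = dplyr::row_number(),
                            .before = 1),
      summary = summary,
      sequences = if (keep_sequences) mat else NULL,
      acceptance_rate = n_sequences / attr(mat, "n_candidates"),
      constraints = constraints,
      seed = as.integer(seed),
      n_trials = as.integer(n_trials)
    ),
    class = "maze_sequence_audit"
  )
}

#' @export
print.maze_sequence_audit <- function(x, ...) {
  cat(sprintf(
    "<maze_sequence_audit> %d sequences x %d trials (acceptance rate %.3f)\n",
    nrow(x$stats), x$n_trials, x$acceptance_rate
  ))
  print(x$summary)
  invisible(x)
}

#' @rdname monte_carlo_audit
#' @param x A `maze_sequence_audit`.
#' @param ... Unused.
#' @export
tidy.maze_sequence_audit <- function(x, ...) x$stats

#' @rdname monte_carlo_audit
#' @export
glance.maze_sequence_audit <- function(x, ...) {
  tibble(
    n_sequences = nrow(x$stats),
    n_trials = x$n_trials,
    acceptance_rate = x$acceptance_rate,
    mean_frac_left = mean(x$stats$frac_left),
    mean_alternation = mean(x$stats$alternation_frac, na.rm = TRUE),
    max_run = max(x$stats$max_run)
  )
}
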