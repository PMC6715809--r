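test_that("policy_choice follows each policy's rule", {
  expect_equal(policy_choice("WIN_STAY", last_rewarded_side = "L"), "L")
  expect_equal(policy_choice("WIN_SHIFT", last_rewarded_side = "L"), "R")
  expect_equal(policy_choice("SPONT_ALTERNATE", last_choice = "R"), "L")
  expect_equal(policy_choice("ALWAYS_LEFT"), "L")
  expect_equal(policy_choice("ALWAYS_RIGHT", last_choice = "L"), "R")
  # no-reward-yet fallback acts on the last choice
  expect_equal(policy_choice("WIN_STAY", last_choice = "R"), "R")
  expect_equal(policy_choice("WIN_SHIFT", last_choice = "R"), "L")
  expect_true(policy_choice("RANDOM") %in% c("L", "R"))
})

test_that("win-shift trace on [L,R,R,L] matches the hand-enumerated oracle", {
  # first choice L, carry rule: hit(L), shift->R hit, shift->L miss (reward
  # stays R), shift->L hit  =>  T T F T, 75%
  res <- simulate_strategy("WIN_SHIFT", c("L", "R", "R", "L"),
                           first_choice = "L")
  expect_equal(res$trials$choice, c("L", "R", "L", "L"))
  expect_equal(res$trials$correct, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(res$percent_correct, 75)
})

test_that("a constant-side policy is perfect on a constant schedule", {
  res <- simulate_strategy("ALWAYS_LEFT", rep("L", 12))
  expect_equal(res$percent_correct, 100)
  expect_equal(simulate_strategy("ALWAYS_LEFT", rep("R", 12))$percent_correct, 0)
})

test_that("simulate_strategy agrees with the naive reference simulator", {
  withr::with_seed(31, {
    for (i in 1:200) {
      n <- sample(4:12, 1)
      cues <- as_side(sample(0:1, n, replace = TRUE))
      fc <- as_side(sample(0:1, 1))
      pol <- sample(setdiff(policies(), "RANDOM"), 1)
      res <- simulate_strategy(pol, cues, first_choice = fc)
      ref <- oracle_policy_trace(pol, cues, fc)
      expect_identical(res$trials$choice, ref)
      expect_equal(res$percent_correct, 100 * mean(ref == cues))
    }
  })
})

test_that("batch policy simulation matches per-schedule simulation row for row", {
  cons <- sequence_constraints()
  seqs <- withr::with_seed(6, morphmaze:::draw_accepted_batch(50, 15, cons))
  for (pol in setdiff(policies(), "RANDOM")) {
    for (fc in 0:1) {
      batch <- morphmaze:::simulate_policy_batch(pol, seqs, first_choice = fc)
      single <- vapply(seq_len(nrow(seqs)), function(i) {
        simulate_strategy(pol, as_side(seqs[i, ]),
                          first_choice = as_side(fc))$percent_correct
      }, numeric(1))
      expect_equal(batch, single)
    }
  }
})

test_that("reactive win-stay/win-shift traces are complementary after trial 1", {
  withr::with_seed(13, {
    for (i in 1:50) {
      cues <- as_side(sample(0:1, 10, replace = TRUE))
      fc <- as_side(sample(0:1, 1))
      stay <- simulate_strategy("WIN_STAY", cues, first_choice = fc,
                                loss_rule = "react")$trials$choice
      shift <- simulate_strategy("WIN_SHIFT", cues, first_choice = fc,
                                 loss_rule = "react")$trials$choice
      expect_identical(stay[1], shift[1])
      expect_true(all(stay[-1] != shift[-1]))
    }
  })
})

test_that("carry-rule win-stay freezes on one side after its first reward", {
  withr::with_seed(14, {
    for (i in 1:50) {
      cues <- as_side(sample(0:1, 12, replace = TRUE))
      tr <- simulate_strategy("WIN_STAY", cues,
                              first_choice = as_side(sample(0:1, 1)))$trials
      first_win <- which(tr$correct)[1]
      if (!is.na(first_win)) {
        expect_true(all(tr$choice[first_win:nrow(tr)] == tr$choice[first_win]))
      }
    }
  })
})

test_that("the random policy scores fifty percent on average", {
  cons <- sequence_constraints()
  pct <- withr::with_seed(55, {
    seqs <- morphmaze:::draw_accepted_batch(400, 25, cons)
    mean(morphmaze:::simulate_policy_batch("RANDOM", seqs))
  })
  expect_lt(abs(pct - 50), 2.5)   # ~3 binomial SEs at 10,000 trials
})

test_that("compliance is 100% against the policy's own responses", {
  cues <- generate_sequence(15, seed = 40)$side
  for (pol in setdiff(policies(), "RANDOM")) {
    res <- simulate_strategy(pol, cues, first_choice = "L")
    expect_equal(compliance(res$trials$choice, res$trials$rewarded, pol), 100)
  }
})

test_that("compliance of strict alternation matches the direct-count oracles", {
  resp <- rep(c("L", "R"), 6)
  out <- rep(TRUE, 12)
  expect_equal(compliance(resp, out, "SPONT_ALTERNATE"), 100)
  # ALWAYS_LEFT predicts L for trials 2..n; count the actual lefts there
  expect_equal(compliance(resp, out, "ALWAYS_LEFT"),
               100 * sum(resp[-1] == "L") / 11)
  expect_error(compliance(resp, out[-1], "WIN_STAY"), "length")
  expect_error(compliance("L", TRUE, "WIN_STAY"), "at least 2")
})

test_that("random responses comply with deterministic policies at chance", {
  withr::with_seed(77, {
    resp <- as_side(sample(0:1, 4000, replace = TRUE))
    out <- sample(c(TRUE, FALSE), 4000, replace = TRUE)
    for (pol in c("WIN_STAY", "SPONT_ALTERNATE", "ALWAYS_LEFT")) {
      expect_lt(abs(compliance(resp, out, pol) - 50), 3)
    }
  })
})

test_that("a ceiling of 100 always certifies", {
  aud <- audit_generator(n_sequences = 50, session_lengths = 10, seed = 2,
                         ceiling = 100)
  expect_true(aud$certified)
})

test_that("a near-alternating generator is exploitable and fails certification", {
  # with alternation forced to [0.95, 1], 25-trial sequences have 23-24
  # switch transitions; enumerate that whole set and brute-force the
  # exploiting policy's mean score as the oracle
  loose <- sequence_constraints(max_run_length = 25,
                                alternation_band = c(0.95, 1),
                                max_side_imbalance = 25)
  stay_pos <- c(0, 1:24)   # 0 = pure alternation, else single stay position
  seq_from <- function(first, stay_at) {
    s <- integer(25)
    s[1] <- first
    for (i in 2:25) s[i] <- if (i - 1 == stay_at) s[i - 1] else 1L - s[i - 1]
    s
  }
  scores <- c()
  for (first in 0:1) for (k in stay_pos) for (fc in c("L", "R")) {
    cues <- as_side(seq_from(first, k))
    tr <- oracle_policy_trace("WIN_SHIFT", cues, fc)
    scores <- c(scores, 100 * mean(tr == cues))
  }
  oracle_mean <- mean(scores)
  expect_gt(oracle_mean, 60)

  aud <- audit_generator(loose, session_lengths = 25, n_sequences = 4000,
                         seed = 19)
  expect_false(aud$certified)
  got <- aud$results$mean_pct_correct[aud$results$policy == "WIN_SHIFT"]
  expect_lt(abs(got - oracle_mean), 3)
})
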