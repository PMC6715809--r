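test_that("validate_sequence rejects long runs, high alternation, imbalance", {
  cons <- sequence_constraints()

  # run of four identical sides
  v <- validate_sequence(c("L", "L", "L", "L", "R", "L", "R", "L", "R", "L"), cons)
  expect_false(v$pass)
  expect_equal(v$stats$max_run, 4)

  # pure alternation: alternation fraction 1, above the band
  v <- validate_sequence(rep(c("L", "R"), 5), cons)
  expect_false(v$pass)
  expect_equal(v$stats$alternation_frac, 1)

  # side imbalance beyond the allowance
  v <- validate_sequence(c("L", "L", "R", "L", "L", "R", "L", "L", "R", "L"),
                         sequence_constraints(alternation_band = c(0, 1)))
  expect_false(v$pass)

  # single trial always passes when an odd count is allowed
  v <- validate_sequence("L", cons)
  expect_true(v$pass)
  expect_equal(v$stats$n, 1)
  expect_equal(v$stats$max_run, 1)
  expect_equal(v$stats$frac_left, 1)

  expect_error(validate_sequence(character(0), cons), "empty")
})

test_that("sequence_stats satisfies the transition-count identity", {
  withr::with_seed(11, {
    for (i in 1:50) {
      n <- sample(2:30, 1)
      s <- as_side(sample(0:1, n, replace = TRUE))
      st <- sequence_stats(s)
      expect_equal(st$n_lr + st$n_rl, round(st$alternation_frac * (n - 1)))
      expect_lte(st$max_run, n)
      expect_gte(st$frac_left, 0)
      expect_lte(st$frac_left, 1)
    }
  })
})

test_that("generated sequences always satisfy their own constraints", {
  cons <- sequence_constraints()
  for (n in c(10, 15, 20, 25)) {
    for (seed in c(1, 7, 1234)) {
      sched <- generate_sequence(n, cons, seed = seed)
      expect_true(validate_sequence(sched$side, cons)$pass)
      expect_equal(nrow(sched), n)
    }
  }
  # and from the batch samplers, in bulk
  mc <- monte_carlo_audit(1000, 25, cons, seed = 3)
  ok <- apply(mc$sequences, 1, function(s) validate_sequence(as_side(s), cons)$pass)
  expect_true(all(ok))
})

test_that("same seed and parameters reproduce the identical sequence", {
  a <- generate_sequence(25, seed = 99)
  b <- generate_sequence(25, seed = 99)
  expect_identical(a$side, b$side)
  expect_identical(attr(a, "n_attempts"), attr(b, "n_attempts"))
  c <- generate_sequence(25, seed = 100)
  expect_false(identical(a$side, c$side))
})

test_that("infeasible constraints raise instead of looping forever", {
  # odd length with zero imbalance allowance can never balance
  cons <- sequence_constraints(max_side_imbalance = 0, max_rejections = 200)
  expect_error(generate_sequence(5, cons, seed = 1), "infeasible")
  expect_error(morphmaze:::draw_accepted_dp(10, 5, cons), "no valid sequence")
})

test_that("acceptance probability at n = 10 matches exhaustive enumeration", {
  cons <- sequence_constraints()
  all10 <- enum_all_sequences(10)
  valid <- apply(all10, 1, oracle_sequence_valid)
  p_enum <- mean(valid)                      # 24 / 1024
  expect_equal(sum(valid), 24)

  # the DP sampler computes the acceptance probability exactly
  mc <- monte_carlo_audit(100, 10, cons, seed = 5)
  expect_equal(mc$acceptance_rate, p_enum, tolerance = 1e-12)

  # expected rejection-sampler attempts ~ 1/p, far below max_rejections
  attempts <- vapply(1:200, function(s) {
    attr(generate_sequence(10, cons, seed = s), "n_attempts")
  }, numeric(1))
  expect_gt(mean(attempts), 0.6 / p_enum)
  expect_lt(mean(attempts), 1.6 / p_enum)
  expect_lt(1 / p_enum, cons$max_rejections / 100)
})

test_that("generator acceptance set equals the validated set (exhaustive, n <= 16)", {
  cons <- sequence_constraints()
  for (n in c(8, 12)) {
    all_n <- enum_all_sequences(n)
    valid_keys <- apply(all_n[apply(all_n, 1, oracle_sequence_valid), ,
                              drop = FALSE], 1, paste, collapse = "")
    # every generated sequence is valid, and sampling covers the whole set
    samp <- withr::with_seed(2, morphmaze:::draw_accepted_batch(4000, n, cons))
    keys <- apply(samp, 1, paste, collapse = "")
    expect_true(all(keys %in% valid_keys))
    expect_setequal(unique(keys), valid_keys)
    # per-sequence rejection sampling lands in the same set
    gen_keys <- vapply(1:50, function(s) {
      paste(side_to_int(generate_sequence(n, cons, seed = s)$side), collapse = "")
    }, character(1))
    expect_true(all(gen_keys %in% valid_keys))
  }
})

test_that("DP sampling is uniform over the acceptance set", {
  cons <- sequence_constraints()
  all10 <- enum_all_sequences(10)
  valid_keys <- apply(all10[apply(all10, 1, oracle_sequence_valid), ,
                            drop = FALSE], 1, paste, collapse = "")
  samp <- withr::with_seed(8, morphmaze:::draw_accepted_dp(24000, 10, cons))
  tab <- table(factor(apply(samp, 1, paste, collapse = ""),
                      levels = valid_keys))
  expect_gt(stats::chisq.test(tab)$p.value, 1e-4)
})

test_that("unconstrained acceptance leaves side frequency at one half", {
  loose <- sequence_constraints(max_run_length = 12,
                                alternation_band = c(0, 1),
                                max_side_imbalance = 12)
  mc <- monte_carlo_audit(10000, 12, loose, seed = 21)
  n_left <- round(sum(mc$stats$frac_left) * 12)
  bt <- stats::binom.test(n_left, 10000 * 12, p = 0.5)
  expect_gt(bt$p.value, 1e-4)
})

test_that("audit aggregates of a single one-trial sequence are that sequence's stats", {
  mc <- monte_carlo_audit(1, 1, sequence_constraints(), seed = 4)
  expect_equal(nrow(mc$stats), 1)
  expect_equal(mc$summary$mean[mc$summary$measure == "max_run"], 1)
  expect_equal(mc$summary$min[mc$summary$measure == "frac_left"],
               mc$summary$max[mc$summary$measure == "frac_left"])
})

test_that("schedule CSV + sidecar round-trips", {
  sched <- generate_sequence(15, seed = 77)
  path <- withr::local_tempfile(fileext = ".csv")
  write_schedule(sched, path)
  back <- read_schedule(path)
  expect_identical(back$side, sched$side)
  expect_identical(attr(back, "seed"), attr(sched, "seed"))
  expect_equal(attr(back, "constraints"), attr(sched, "constraints"))
})
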