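test_that("a correct pre-hint response in phase 1 earns three pellets", {
  res <- run_trial("L", phase_config(1), perfect_subject(800))
  expect_equal(res$record$outcome, "CORRECT")
  expect_equal(res$record$pellets, 3)
  expect_equal(res$record$reaction_time_ms, 800)
  expect_true("FEEDER_DISPENSE" %in% res$events$kind)
})

test_that("a silent subject times out with zero pellets", {
  cfg <- phase_config(7)
  res <- run_trial("R", cfg, function(cued, ctx) NULL)
  expect_equal(res$record$outcome, "TIMEOUT")
  expect_equal(res$record$pellets, 0)
  expect_true(is.na(res$record$chosen_side))
  expect_true(is.na(res$record$reaction_time_ms))
  to <- res$events[res$events$kind == "TIMEOUT", ]
  expect_equal(to$t_ms, cfg$timeout_ms)
  # a response slower than the timeout is a timeout too
  res2 <- run_trial("R", cfg, function(cued, ctx)
    list(choice = "R", latency_ms = cfg$timeout_ms + 1))
  expect_equal(res2$record$outcome, "TIMEOUT")
})

test_that("hint trials pay a single pellet to hint-followers", {
  cfg <- phase_config(1)
  # responds only after the hint, to the cued side: 1 pellet, no feeder event
  res <- run_trial("L", cfg, perfect_subject(1500),
                   is_hint = TRUE, hint_delay_ms = 1000)
  expect_equal(res$record$pellets, 1)
  expect_equal(res$record$outcome, "CORRECT")
  expect_false(res$record$responded_pre_hint)
  expect_true("HINT_DISPENSE" %in% res$events$kind)
  expect_false("FEEDER_DISPENSE" %in% res$events$kind)
  # responds before the hint: full reward, no hint dispensed
  res2 <- run_trial("L", cfg, perfect_subject(500),
                    is_hint = TRUE, hint_delay_ms = 1000)
  expect_equal(res2$record$pellets, 3)
  expect_true(res2$record$responded_pre_hint)
  expect_false("HINT_DISPENSE" %in% res2$events$kind)
})

test_that("negative latency from the subject callback is rejected", {
  expect_error(
    run_trial("L", phase_config(1),
              function(cued, ctx) list(choice = "L", latency_ms = -5)),
    "negative"
  )
})

test_that("sessions deliver the protocol's trial counts", {
  s7 <- run_session(7, perfect_subject(), seed = 1)
  expect_equal(nrow(s7$trials), 100)            # 4 blocks x 25 trials
  expect_equal(unique(table(s7$trials$block)), 25L)
  s1 <- run_session(1, perfect_subject(), seed = 1)
  expect_equal(nrow(s1$trials), 40)             # 4 blocks x 10 trials
  expect_true(all(s7$trials$outcome == "CORRECT"))
})

test_that("block length must match the phase's trials per block", {
  sched <- generate_sequence(10, seed = 2)
  expect_error(run_block(sched, phase_config(7), perfect_subject()),
               "25")
})

test_that("event logs are well-formed for arbitrary subjects", {
  messy_subject <- function(cued, ctx) {
    u <- runif(1)
    if (u < 0.15) return(NULL)
    list(choice = as_side(sample(0:1, 1)),
         latency_ms = runif(1, 0, ctx$timeout_ms * 1.05))
  }
  s <- withr::with_seed(23, run_session(phase_config(1), messy_subject,
                                        seed = 31, day_in_phase = 4))
  per_trial <- split(s$events, list(s$events$block, s$events$trial),
                     drop = TRUE)
  for (ev in per_trial) {
    expect_true(all(diff(ev$t_ms) >= 0))                # time non-decreasing
    expect_equal(sum(ev$kind == "NOSE_POKE"), 1)
    expect_equal(sum(ev$kind == "TRIAL_END"), 1)
    expect_equal(sum(ev$kind == "CUE_ON"), 1)
    expect_gt(which(ev$kind == "CUE_ON"), which(ev$kind == "NOSE_POKE"))
    expect_lte(sum(ev$kind %in% c("SENSOR_LEFT", "SENSOR_RIGHT")), 1)
  }
  # reaction time is exactly sensor timestamp minus nose-poke timestamp
  for (ev in per_trial) {
    sensor_t <- ev$t_ms[ev$kind %in% c("SENSOR_LEFT", "SENSOR_RIGHT")]
    if (length(sensor_t) == 1) {
      rec <- s$trials[s$trials$block == ev$block[1] &
                        s$trials$trial_index == ev$trial[1], ]
      expect_equal(rec$reaction_time_ms,
                   sensor_t - ev$t_ms[ev$kind == "NOSE_POKE"])
    }
  }
})

test_that("trial records reconstructed from events equal the direct records", {
  messy_subject <- function(cued, ctx) {
    if (runif(1) < 0.1) return(NULL)
    list(choice = as_side(sample(0:1, 1)),
         latency_ms = runif(1, 100, ctx$timeout_ms))
  }
  s <- withr::with_seed(99, run_session(phase_config(1), messy_subject,
                                        seed = 17, day_in_phase = 5))
  rec <- trial_records_from_events(s$events, s$config)
  cols <- c("block", "trial_index", "cued_side", "chosen_side",
            "reaction_time_ms", "pellets", "outcome", "is_hint",
            "responded_pre_hint", "t_start", "t_end")
  direct <- dplyr::arrange(s$trials[, cols], block, trial_index)
  rebuilt <- dplyr::arrange(rec[, cols], block, trial_index)
  expect_equal(as.data.frame(rebuilt), as.data.frame(direct),
               ignore_attr = TRUE)
})

test_that("JSONL event logs round-trip unchanged", {
  s <- run_session(2, perfect_subject(600), seed = 8, day_in_phase = 2)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_event_log(s, path)
  log <- read_event_log(path)
  expect_equal(log$header$phase, 2)
  expect_equal(log$header$seed, 8)
  expect_equal(as.data.frame(log$events), as.data.frame(s$events),
               ignore_attr = TRUE)
  # and the reconstructed records still match
  cfg <- phase_config(log$header$phase)
  rec <- trial_records_from_events(log$events, cfg)
  expect_equal(nrow(rec), nrow(s$trials))
})

test_that("inter-trial gap equals the subject's return latency", {
  rigid <- structure(list(
    respond = function(cued, ctx) list(choice = cued, latency_ms = 500),
    begin_block = function() invisible(NULL),
    notify = function(choice, rewarded) invisible(NULL),
    return_latency = function() 2500
  ), class = "maze_subject")
  blk <- run_block(generate_sequence(10, seed = 5), phase_config(1), rigid)
  starts <- blk$trials$t_start
  ends <- blk$trials$t_end
  expect_equal(starts[-1], ends[-10] + 2500)
})
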