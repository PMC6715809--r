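---
title: "Scheduling, simulating and scoring an automated maze-training task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scheduling, simulating and scoring an automated maze-training task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphmaze)
library(dplyr)
```

## The task and what this package models

morphmaze implements the software side of an automated training system for a
two-alternative forced-choice (2AFC) tone-to-place task in rats. The animal
nose-pokes to start a trial, hears a 7 Hz or 14 Hz cue tone indicating which
of two reward areas will pay out, and must cross the corresponding reward-area
sensor within the trial timeout. Training is incremental: seven phases take
the apparatus from a compact operant box (phases 1–4, cue training with hint
trials) to a full-size maze with an 80 cm central arm (phase 7), adding a
working-memory component as the distance between cue and reward grows. A
session is four blocks of 10–25 scheduled trials depending on phase.

The package covers everything that is software: constrained trial-sequence
generation and its statistical certification, the discrete-event trial state
machine and its JSON-lines event log, a virtual-rat simulator used as the test
fixture for the whole pipeline, the three trial-scoring methods and rolling
learning curves, and the analyses that compare scoring methods and
reaction-time distributions. Hardware (sensors, feeders, micro-controllers)
and real-animal data are out of scope.

## Constrained pseudorandom schedules

Each block's cue sequence is drawn i.i.d. uniform over left/right and
accepted only if

* no side repeats for more than `max_run_length = 3` consecutive trials,
* the fraction of side-switch transitions lies in
  `alternation_band = [0.35, 0.45]`, and
* left/right counts differ by at most `max_side_imbalance = 1`.

Rejection is of the whole sequence, never a local repair: repairing a failed
sequence in place would bias its transition statistics, which are exactly
what the constraints control. The run-length cap stops side biases from
paying off; the alternation band is centred on a 40/60 switch/stay ratio —
rodents alternate spontaneously, so the schedule must actively over-represent
same-side transitions to force attention to the cue; the balance constraint
counterbalances sides within a block. The precise windowing of the published
alternation rule is not available to us, so a global alternation fraction
with a configurable band is used and documented as this package's choice.

```{r}
sched <- generate_sequence(25, seed = 7)
sched
```

`generate_sequence()` seeds one RNG per block and stores the seed, attempt
count and constraints in the schedule (and in the CSV sidecar written by
`write_schedule()`), so any block is replayable for audit.

### Auditing the generator

`monte_carlo_audit()` regenerates schedules en masse (the design-time audit
used 10,000 draws) and tabulates side frequency, alternation fraction,
longest run and directional transition counts. Under the default constraints
the acceptance probability of a 25-trial candidate is about
`r signif(monte_carlo_audit(10, 25, seed = 1)$acceptance_rate, 2)`.
Rejection sampling at that rate is exact but wasteful at audit scale, so the
batch samplers use an equivalent exact method: a backward dynamic program
counts, for every state (trial, current side, run length, switch count, left
count), the number of valid completions, and sequences are drawn forward
with probabilities proportional to those counts. This samples the same
distribution rejection sampling does — the uniform distribution over the
acceptance set — and the equivalence is property-tested against exhaustive
enumeration at small block lengths. When the constraint state space would be
too large for the table the audit falls back to chunked rejection.

```{r}
glance(monte_carlo_audit(10000, 25, seed = 1))
```

### Null-strategy certification

Rats are excellent at exploiting sequence patterns through reward feedback
alone. `audit_generator()` therefore simulates six cue-ignoring policies
against freshly generated schedules at every block length used in training:
constant side biases, win-stay, win-shift, spontaneous alternation, and
random choice. A policy sees only its own reward history, never the cue. The
generator is certified when no policy's mean percent of rewarded trials
exceeds 60% at any session length.

```{r}
aud <- audit_generator(n_sequences = 2000, seed = 3)
aud
```

Two conventions exist for win-stay/win-shift after an unrewarded trial, and
the choice matters. Under the default `loss_rule = "carry"` the policies act
on the most recent rewarded side, carried across losses; carry-rule win-stay
then provably collapses into a constant side bias after its first reward
(its remembered side only ever updates to the side it already occupies), so
its audit mean equals the accepted sequences' side frequency, about 50%.
Under `loss_rule = "react"` the policies respond to the previous trial's own
outcome (win-stay/lose-shift and win-shift/lose-stay, the classic pair), and
the two traces are exactly complementary from trial 2 onward when started
from the same first choice — a property the test suite asserts. Reactive
win-shift is also the policy that breaks a near-alternating generator
(alternation band forced to [0.95, 1] fails certification), which is the
behavioral reason high-switch schedules must be filtered out.

`compliance()` scores an observed response stream against a policy's
trial-by-trial predictions, seeding the policy state from the animal's
response to the first cue of the block and predicting each later trial from
the animal's actual choice/reward history.

## The trial state machine

`run_trial()` emits a canonical event stream per trial: `NOSE_POKE` and
`CUE_ON` at trial start, then either a reward-area `SENSOR_*` crossing at the
response latency (with a `FEEDER_DISPENSE` when the choice is correct and
pre-hint) or a `TIMEOUT` at the phase's limit, closed by a `TRIAL_END`
carrying the outcome. Reaction time is defined as the first sensor timestamp
minus the nose-poke timestamp, exactly. Timestamps are integer-valued
milliseconds on a simulated clock from session start; the next trial begins
at the previous trial's end plus the subject's return-to-start latency.

Hint trials (phases 1–2) dispense a single pellet at the cued side after a
delay unless the animal has already responded; a correct pre-hint response
pays the full phase reward (3 pellets in phase 1, 2 in phases 2–5, 1 in
phases 6–7), while a hint-follower collects at most the one hint pellet.
That asymmetry is what lets reward-count scoring reject guided trials.

Defaults that the published protocol does not pin down numerically are
explicit stand-ins, all overridable through `phase_config()`:

* **Timeouts** — 6 s is stated for phase 1. We keep 6 s through phases 1–4
  and scale with the growing maze to 8 s and 10 s in phases 6–7 (trials
  lengthen as the central arm grows from 20 to 80 cm).
* **Hint schedule** — hints are described as used "initially", heavily on
  the first two days: we hint every trial on phase-1 days 1–2, then 15% of
  trials (10% in phase 2), with the cue-to-hint delay ramping linearly from
  0 to 2 s over the first five phase-1 sessions.
* **Tone map** — 7 Hz→left, 14 Hz→right by default, per-subject
  configurable for counterbalancing.

The head-turn/body-turn response criteria of phases 2–4 are observational
and not sensor-detectable; they are modeled as the subject callback's
pre-hint response with the same correct/incorrect semantics. This is a known
limitation, not a claim about the physical system.

The JSONL log (`write_event_log()`/`read_event_log()`) is lossless for
scoring: `trial_records_from_events()` rebuilds every per-trial record from
raw events (the `TRIAL_END` payload carries the hint flag, since a hint
trial answered before its hint leaves no other trace), and a property test
asserts the rebuilt records equal the directly returned ones.

## The virtual rat

`virtual_subject()` is the fixture generator: a stochastic animal with the
statistical structure the analyses assume, not a biophysical model. Per
trial it times out with probability `p_timeout`, answers from a cue-ignoring
lapse policy with probability `p_strategy_lapse` (spontaneous alternation by
default), and otherwise follows the cue with accuracy

$$p(\mathrm{day}) = p_\mathrm{start} + (p_\mathrm{asymptote} -
p_\mathrm{start})\,(1 - e^{-\lambda\,\mathrm{day}}),$$

a saturating learning curve over global training days. Latencies are
log-normal, parameterized by their mode because modes are the reported
summary of the empirical densities: the mode is phase-specific and grows
with maze length (1.2/1.5/1.8 s in phases 5–7, within the observed 1–2 s
range), and the log-scale spread is smaller on correct trials
(`rt_sigma_correct = 0.25`) than on incorrect ones
(`rt_sigma_incorrect = 0.45`), since incorrect trials mix strategy-fast and
distracted-slow responses. Draws are truncated at the phase timeout via the
inverse CDF. Return-to-start latencies come from a separate log-normal and
only shape timestamps.

### Calibration of the defaults

The defaults were calibrated analytically, before any simulation, to the
study conditions the training produced: realized accuracy (timeouts scored
incorrect, hint trials excluded) averaging about 59% over phase 1 and about
87% over phase 7 on the default 45-day calendar
(`training_schedule()`, 6/5/5/5/6/8/10 days per phase, most time on early
cue training and the full task). Because timeouts and lapses degrade
realized accuracy below $p(\mathrm{day})$, hitting 87% in phase 7 forces a
high asymptote; the solution used is $p_\mathrm{start} = 0.50$,
$p_\mathrm{asymptote} = 0.95$, $\lambda = 0.06\,\mathrm{day}^{-1}$,
$p_\mathrm{timeout} = 0.02$, $p_\mathrm{lapse} = 0.05$. The acceptance test
checks the simulated phase-1 and phase-7 accuracies against those targets
with a ±5-point band, acknowledging that the published span comes from four
real animals.

What the virtual rat does **not** emulate: positional trajectories and
side-arm excursions, tail-triggered sensor artifacts (the very reason
sensor scores are unreliable in phases 1–4 — simulated sensor and manual
scores coincide exactly once hints and timeouts are absent), motivational
drift within a session, and individual differences beyond the shared
parameter set. Tests passing on this fixture therefore validate the
*pipeline* — schedules, state machine, scoring, statistics — not any claim
about real rats.

## Scoring

Three methods score the same trials:

* **manual-equivalent** — outcome-based: the response was correct and came
  before any hint; hint trials excluded by default (as in hand scoring).
* **reward** — pellet count against the per-phase threshold (3/2/2/2/2/1/1).
  Hint trials stay in by default and score incorrect, since the hint pays
  only one pellet.
* **sensor** — first reward-area sensor crossing versus the cued side;
  timeouts incorrect. Hint trials stay in by default, which is what inflates
  early sensor scores: a guided animal still trips the correct sensor.

`daily_scores()` aggregates to animal-days and applies a trailing 3-day
rolling mean with partial windows at the series start (so curves begin on
day 1; whether the published average was centred or trailing is unstated,
and trailing is this package's documented choice). Sensor scores for phases
1–4 carry a `sensor_reliable = FALSE` flag and a warning. `phase_means()`
pools each animal's days within a phase, trial-weighted — one point per
animal per phase, the unit of the concordance analysis.

```{r}
trials <- simulate_training(n_animals = 2,
                            schedule = training_schedule()[c(1:3, 36:38), ],
                            seed = 42)
daily_scores(trials, "reward") |> head()
```

## Analyses

**Concordance.** `concordance()` regresses one method's per-animal-per-phase
means on another's in exactly two passes: fit, flag points farther than
3 × SD(|residuals|) from the fit, refit once through the rest. Two details
are deliberate and literal: the threshold scale is the standard deviation of
the *absolute* residuals (for Gaussian noise that is ≈0.60 of the residual
SD, so the effective cut sits near 1.8σ — noticeably stricter than a 3σ
residual rule), and there is no iteration beyond the single refit. The
slope/intercept/R² of the refit are reported with the outlier mask;
`autoplot()` draws outliers as open circles against the unity line.

**Reaction times.** `rt_summaries()` restricts to the full-task phases 5–7
(earlier phases have unreliable sensor timing) and always drops timed-out
trials — their recorded time is the timeout threshold, not behavior. Modes
are estimated as the midpoint of the tallest 100 ms histogram bin (bin
width configurable; ties break toward the earlier bin), spreads as the
interquartile range with linear interpolation between order statistics
(quantile type 7 — stated because IQRs depend on the rule). `rt_compare()`
is the two-sided two-sample Kolmogorov–Smirnov test, exact when both
samples have fewer than 30 observations.

```{r}
trials7 <- simulate_training(n_animals = 2,
                             schedule = training_schedule()[36:45, ],
                             seed = 9)
rt_summaries(trials7, by_phase = FALSE) |> select(-samples)
```

## Numerical and design choices, collected

* Whole-sequence rejection; the audit path samples the identical
  distribution by exact DP and is property-tested against enumeration.
* `max_rejections = 100,000` per block; expected attempts at the default
  constraints stay below ~3,500 at the hardest length (n = 25).
* Degenerate inputs: empty sequences, all-outlier regressions, sub-2-point
  KS samples, negative latencies and schedule/phase length mismatches all
  raise immediately with explicit messages.
* Seeds: every stochastic entry point requires a seed (block schedules,
  sessions, audits, the training simulator); session seeds derive block
  seeds, the master training seed derives session seeds, and all are kept
  below 2³¹.
* Problem sizes in the shipped tests and acceptance script: audits of
  10,000 sequences per block length, training simulations of 2–4 animals
  over the 45-day calendar, and distribution checks at 1,000–2,000 draws
  per class — sizes chosen to keep Monte-Carlo error well inside the
  stated tolerance bands.

## Limitations

Fig-for-fig numerical results of the original study (regression slopes on
real animals, real IQRs and KS p-values) depend on the four rats' data and
are not reproduced here; the package reproduces the *procedures* and
certifies them on synthetic subjects. The per-phase timeouts beyond phase 1
and the exact supplementary alternation rule are declared stand-ins. Sensor
unreliability in phases 1–4 is flagged, not simulated.
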