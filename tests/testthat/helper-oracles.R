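# Independent oracles used across the suite. These deliberately re-derive
# results through the most direct route available (exhaustive enumeration,
# closed forms, naive loops) and share no code with the implementation paths
# they check.

# all 2^n side sequences as an (2^n x n) 0/1 matrix
enum_all_sequences <- function(n) {
  as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
}

# direct re-statement of the constraint rules on one 0/1 vector
oracle_sequence_valid <- function(s, max_run = 3, band = c(0.35, 0.45),
                                  imbalance = 1) {
  n <- length(s)
  if (abs(sum(s == 0) - sum(s == 1)) > imbalance) return(FALSE)
  run <- 1
  longest <- 1
  if (n > 1) {
    for (i in 2:n) {
      run <- if (s[i] == s[i - 1]) run + 1 else 1
      longest <- max(longest, run)
    }
    if (longest > max_run) return(FALSE)
    af <- sum(s[-1] != s[-n]) / (n - 1)
    if (af < band[1] || af > band[2]) return(FALSE)
  }
  TRUE
}

# naive reference simulator for the null policies (carry loss rule),
# written as a direct trial loop independent of simulate_strategy()
oracle_policy_trace <- function(policy, cues, first_choice) {
  comp <- function(s) if (s == "L") "R" else "L"
  n <- length(cues)
  lc <- NULL
  lr <- NULL
  choices <- character(n)
  for (i in seq_len(n)) {
    choices[i] <- if (i == 1) {
      first_choice
    } else {
      switch(policy,
        ALWAYS_LEFT = "L",
        ALWAYS_RIGHT = "R",
        SPONT_ALTERNATE = comp(lc),
        WIN_STAY = if (!is.null(lr)) lr else lc,
        WIN_SHIFT = if (!is.null(lr)) comp(lr) else comp(lc)
      )
    }
    if (choices[i] == cues[i]) lr <- choices[i]
    lc <- choices[i]
  }
  choices
}

# closed-form simple linear regression (normal equations)
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept,
       r_squared = 1 - ss_res / ss_tot, residuals = y - fitted)
}

# sorted-order-statistic quantile with linear interpolation (type 7):
# h = (n - 1) p + 1; interpolate between floor(h) and ceiling(h)
oracle_quantile <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  xs[lo] + (h - lo) * (xs[min(lo + 1, length(xs))] - xs[lo])
}

# a deterministic always-correct subject callback for engine tests
perfect_subject <- function(latency_ms = 800) {
  function(cued, ctx) list(choice = cued, latency_ms = latency_ms)
}
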