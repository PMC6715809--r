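Package: morphmaze
Title: Automated Incremental Maze Training: Trial Scheduling, Simulation and
    Behavioral Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Software components of an automated rodent maze-training system for
    two-alternative forced-choice tasks: constrained pseudorandom trial-sequence
    generation with Monte-Carlo auditing against null response strategies
    (win-stay, win-shift, spontaneous alternation and side biases), a
    discrete-event trial state machine covering seven incremental training
    phases with hint trials and timeouts, a virtual-rat simulator with a
    parametric learning curve and log-normal reaction times, automated
    behavioral scoring by reward count and by sensor crossings with rolling
    learning curves, and analysis tools for score-method concordance
    (regression with residual-based outlier rejection) and reaction-time
    distribution comparison (modes, interquartile ranges, two-sample
    Kolmogorov-Smirnov tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
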