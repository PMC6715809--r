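#' Read and write block schedules
#'
#' Schedules are stored as plain CSV with header `trial_index,side`
#' (0-based index, side `L`/`R`) plus a JSON sidecar (`<path>.json`) holding
#' the seed and constraints so the block can be regenerated and audited.
#'
#' @param schedule A `maze_schedule` from [generate_sequence()].
#' @param path CSV file path.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns a `maze_schedule` (attributes restored from the sidecar when
#'   present).
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write_schedule(generate_sequence(10, seed = 3), p)
#' read_schedule(p)
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "maze_schedule"))
  utils::write.csv(
    as.data.frame(schedule[c("trial_index", "side")]),
    path, row.names = FALSE, quote = FALSE
  )
  cons <- attr(schedule, "constraints")
  jsonlite::write_json(
    list(
      seed = attr(schedule, "seed"),
      n_attempts = attr(schedule, "n_attempts"),
      constraints = list(
        max_run_length = cons$max_run_length,
        alternation_band = cons$alternation_band,
        max_side_imbalance = cons$max_side_imbalance,
        max_rejections = cons$max_rejections
      )
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("trial_index", "side") %in% names(df)))
  sides <- as_side(df$side)
  out <- tibble(trial_index = as.integer(df$trial_index), side = sides)
  seed <- NA_integer_
  attempts <- NA_integer_
  cons <- sequence_constraints()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    seed <- as.integer(meta$seed)
    attempts <- as.integer(meta$n_attempts)
    cons <- sequence_constraints(
      max_run_length = meta$constraints$max_run_length,
      alternation_band = meta$constraints$alternation_band,
      max_side_imbalance = meta$constraints$max_side_imbalance,
      max_rejections = meta$constraints$max_rejections
    )
  }
  structure(
    out,
    class = c("maze_schedule", class(out)),
    seed = seed,
    constraints = cons,
    n_attempts = attempts,
    stats = sequence_stats(sides)
  )
}
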