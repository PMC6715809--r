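#' Maze sides
#'
#' Trials in the two-alternative forced-choice task cue one of two reward
#' areas, left (`"L"`) or right (`"R"`). Sides are represented throughout the
#' package as single characters; on disk (schedule CSVs, event logs) they may
#' also be serialized as integers, 0 for left and 1 for right.
#'
#' @param x A character vector of `"L"`/`"R"`, or an integer vector of 0/1.
#' @return `as_side()` returns a character vector of `"L"`/`"R"`;
#'   `side_complement()` returns the opposite side(s); `side_to_int()` the
#'   0/1 encoding.
#' @examples
#' side_complement(c("L", "R"))
#' as_side(c(0L, 1L))
#' @export
as_side <- function(x) {
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1), na.rm = TRUE)) {
      abort("integer-coded sides must be 0 (left) or 1 (right)")
    }
    return(c("L", "R")[x + 1L])
  }
  x <- as.character(x)
  ok <- x %in% c("L", "R") | is.na(x)
  if (!all(ok)) {
    abort(paste0("invalid side value(s): ", paste(unique(x[!ok]), collapse = ", ")))
  }
  x
}

#' @rdname as_side
#' @export
side_complement <- function(x) {
  x <- as_side(x)
  unname(c(L = "R", R = "L")[x])
}

#' @rdname as_side
#' @export
side_to_int <- function(x) {
  x <- as_side(x)
  ifelse(is.na(x), NA_integer_, ifelse(x == "R", 1L, 0L))
}
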