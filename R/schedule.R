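#' Build the 68-trial spatial-span schedule
#'
#' Constructs the fixed trial order used by the span task: a 16-trial series
#' of set-size blocks (four trials each of set sizes 6, 8, 5, 7) repeated
#' four times, with a pair of easy set-size-3 catch trials between the first
#' and second series and between the third and fourth, and a rest break at
#' the midpoint (after trial 34). Every participant sees the identical
#' order, so between-participant differences in trajectories cannot be due
#' to differing histories of trial difficulty.
#'
#' @return A tibble with one row per trial and columns `trial_index`
#'   (1--68), `set_size` (3, 5, 6, 7 or 8), `is_catch`, `block_index`
#'   (series number 1--4; catch trials take the series they follow) and
#'   `break_after`.
#' @examples
#' sched <- build_schedule()
#' table(sched$set_size)
#' @export
build_schedule <- function() {
  series <- rep(c(6L, 8L, 5L, 7L), each = 4L)
  set_size <- c(series, 3L, 3L, series, series, 3L, 3L, series)
  block <- c(rep(1L, 18L), rep(2L, 16L), rep(3L, 18L), rep(4L, 16L))
  tibble::tibble(
    trial_index = seq_along(set_size),
    set_size = set_size,
    is_catch = set_size == 3L,
    block_index = block,
    break_after = seq_along(set_size) == 34L
  )
}

#' Validate a trial schedule
#'
#' Checks a schedule table against the design invariants: 68 contiguous
#' trials, 16 trials of each main set size and 4 catch trials of set size
#' 3, set sizes appearing in blocks of four in the order 6, 8, 5, 7 within
#' each series, and no run of identical main set sizes longer than four.
#'
#' @param schedule A data frame as returned by [build_schedule()].
#' @return A character vector of violation descriptions; empty when the
#'   schedule satisfies every invariant.
#' @examples
#' validate_schedule(build_schedule())
#' @export
validate_schedule <- function(schedule) {
  v <- character()
  need <- c("trial_index", "set_size", "is_catch")
  if (!all(need %in% names(schedule))) {
    return(paste("missing columns:", paste(setdiff(need, names(schedule)), collapse = ", ")))
  }
  if (nrow(schedule) != 68L) {
    v <- c(v, sprintf("trial count: expected 68 trials, found %d", nrow(schedule)))
  }
  if (!identical(as.integer(schedule$trial_index), seq_len(nrow(schedule)))) {
    v <- c(v, "trial index: not contiguous 1-based")
  }
  counts <- table(factor(schedule$set_size, levels = c(3, 5, 6, 7, 8)))
  if (counts[["3"]] != 4L) {
    v <- c(v, sprintf("catch count: expected 4 set-size-3 trials, found %d", counts[["3"]]))
  }
  bad <- names(counts)[counts[c("5", "6", "7", "8")] != 16L]
  for (s in intersect(c("5", "6", "7", "8"), bad)) {
    v <- c(v, sprintf("set-size count: expected 16 trials of set size %s, found %d", s, counts[[s]]))
  }
  if (!all(schedule$is_catch == (schedule$set_size == 3L))) {
    v <- c(v, "catch flag: is_catch inconsistent with set_size == 3")
  }
  main <- schedule$set_size[!schedule$is_catch]
  runs <- rle(main)
  if (any(runs$lengths != 4L)) {
    v <- c(v, "block length: runs of identical main set sizes must have length exactly 4")
  }
  if (length(main) >= 16L &&
      !all(runs$values[seq_len(min(4L, length(runs$values)))] == c(6L, 8L, 5L, 7L))) {
    v <- c(v, "block order: set sizes must cycle 6, 8, 5, 7 within each series")
  } else if (length(runs$values) == 16L &&
             !all(runs$values == rep(c(6L, 8L, 5L, 7L), 4L))) {
    v <- c(v, "block order: set sizes must cycle 6, 8, 5, 7 within each series")
  }
  catch_pos <- schedule$trial_index[schedule$is_catch]
  if (nrow(schedule) == 68L && counts[["3"]] == 4L &&
      !identical(as.integer(catch_pos), c(17L, 18L, 51L, 52L))) {
    v <- c(v, "catch placement: catch pairs belong between series 1/2 and series 3/4")
  }
  v
}
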