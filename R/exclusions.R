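#' Highest score still consistent with chance guessing
#'
#' For an exact one-tailed binomial test against a guessing rate, returns
#' the largest integer score `k` whose upper-tail probability
#' `P(X >= k | n_items, guess_rate)` is at least `alpha`. Scores at or
#' below this threshold are *not* significantly above chance and mark a
#' participant for exclusion.
#'
#' @param n_items Number of test items (>= 1).
#' @param guess_rate Per-item guessing probability (matrix-reasoning tasks
#'   with eight response options: 0.125).
#' @param alpha One-tailed significance level.
#' @return Integer threshold in `0:n_items`.
#' @examples
#' binomial_chance_threshold(10, 0.5, 0.05) # 8
#' @export
binomial_chance_threshold <- function(n_items, guess_rate = 0.125, alpha = 0.05) {
  if (n_items < 1 || n_items != round(n_items)) {
    stop("`n_items` must be a positive integer.", call. = FALSE)
  }
  if (guess_rate <= 0 || guess_rate >= 1) {
    stop("`guess_rate` must be strictly between 0 and 1.", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be strictly between 0 and 1.", call. = FALSE)
  }
  k <- 0:n_items
  upper_tail <- stats::pbinom(k - 1, n_items, guess_rate, lower.tail = FALSE)
  max(k[upper_tail >= alpha])
}

#' Screen a cohort for chance-level performance
#'
#' Applies the two exclusion rules: an exact one-tailed binomial test
#' against the matrix-reasoning guessing rate (per task, given that task's
#' item count), and the 50% criterion on spatial-span catch-trial accuracy
#' (strictly below 0.5 excludes; exactly 0.5 is retained).
#'
#' @param matrix_scores Long tibble with columns `participant_id`, `task`,
#'   `score` (integer number correct).
#' @param item_counts Named vector giving each task's item count; every
#'   task appearing in `matrix_scores` must be named (a missing count is a
#'   configuration error).
#' @param catch Optional tibble with `participant_id` and `catch_accuracy`
#'   in \[0, 1\] (see [catch_accuracy()]).
#' @param guess_rate,alpha Passed to [binomial_chance_threshold()].
#' @param catch_criterion Catch-trial accuracy below which a participant is
#'   excluded.
#' @return Tibble of decisions: `participant_id`, `rule` (`matrix-chance` /
#'   `catch-chance`), `task`, `score`, `threshold`, `excluded`.
#' @examples
#' scores <- tibble::tibble(participant_id = c(1, 1, 2, 2),
#'                          task = rep(c("sandia", "ucmrt"), 2),
#'                          score = c(10, 11, 2, 3))
#' screen_cohort(scores, item_counts = c(sandia = 14, ucmrt = 17))
#' @export
screen_cohort <- function(matrix_scores = NULL, item_counts = NULL, catch = NULL,
                          guess_rate = 0.125, alpha = 0.05, catch_criterion = 0.5) {
  out <- list()
  if (!is.null(matrix_scores) && nrow(matrix_scores)) {
    tasks <- unique(matrix_scores$task)
    missing <- setdiff(tasks, names(item_counts))
    if (length(missing)) {
      stop(sprintf("no item count configured for task(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    if (any(matrix_scores$score < 0) || any(matrix_scores$score != round(matrix_scores$score))) {
      stop("scores must be nonnegative integers.", call. = FALSE)
    }
    thresholds <- vapply(tasks, function(tk) {
      binomial_chance_threshold(item_counts[[tk]], guess_rate, alpha)
    }, 0)
    out$matrix <- matrix_scores |>
      dplyr::mutate(
        rule = "matrix-chance",
        threshold = thresholds[match(.data$task, tasks)],
        excluded = .data$score <= .data$threshold
      ) |>
      dplyr::select("participant_id", "rule", "task", "score", "threshold", "excluded")
  }
  if (!is.null(catch) && nrow(catch)) {
    if (any(catch$catch_accuracy < 0 | catch$catch_accuracy > 1)) {
      stop("`catch_accuracy` must lie in [0, 1].", call. = FALSE)
    }
    out$catch <- catch |>
      dplyr::transmute(
        .data$participant_id,
        rule = "catch-chance", task = NA_character_,
        score = .data$catch_accuracy, threshold = catch_criterion,
        excluded = .data$catch_accuracy < catch_criterion
      )
  }
  if (!length(out)) {
    return(tibble::tibble(participant_id = integer(), rule = character(),
                          task = character(), score = numeric(),
                          threshold = numeric(), excluded = logical()))
  }
  dplyr::bind_rows(out)
}

#' Participants excluded by any screening rule
#'
#' @param decisions Output of [screen_cohort()].
#' @return Vector of excluded participant ids.
#' @export
excluded_participants <- function(decisions) {
  sort(unique(decisions$participant_id[decisions$excluded]))
}
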