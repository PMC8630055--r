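#' Simulate a synthetic cohort over the 68-trial schedule
#'
#' Draws participant-level trajectory parameters and Gf scores from the
#' configured population, then generates every mouse click of the span
#' task: for each scheduled trial the predicted accuracy comes from
#' [predict_accuracy()] (participant parameters plus population set-size
#' slopes), and `set_size` conditionally independent Bernoulli clicks are
#' drawn at that probability. Each participant therefore contributes 428
#' click records (416 from the main set sizes, 12 from catch trials). The
#' whole cohort is reproducible from `config$seed`.
#'
#' @param config A [population_config()].
#' @return An object of class `wm_cohort`: a list with `trials` (click-level
#'   tibble: `participant_id`, `trial_index`, `set_size`, `click_index`,
#'   `click_correct`, `feedback`, `task_order`), `participants` (truth table
#'   with `gf`), `schedule` and `config`.
#' @examples
#' cohort <- simulate_cohort(population_config(n_participants = 3, seed = 2))
#' nrow(cohort$trials) # 3 * 428
#' @export
simulate_cohort <- function(config = population_config()) {
  stopifnot(inherits(config, "wm_pop_config"))
  sched <- build_schedule()
  truth <- generate_gf(sample_population_params(config), config)
  n <- nrow(truth)

  per_part <- tidyr::crossing(participant_id = truth$participant_id,
                              sched[, c("trial_index", "set_size")])
  idx <- match(per_part$participant_id, truth$participant_id)
  p <- predict_accuracy(
    per_part$trial_index, per_part$set_size,
    list(sigma0 = truth$sigma0[idx], alpha0 = truth$alpha0[idx], rho = truth$rho[idx],
         sigma_slope = config$start_slope, alpha_slope = config$asym_slope)
  )
  clicks <- per_part[rep(seq_len(nrow(per_part)), per_part$set_size), ]
  clicks$click_index <- stats::ave(seq_len(nrow(clicks)), clicks$participant_id,
                                   clicks$trial_index, FUN = seq_along)
  p_click <- rep(p, per_part$set_size)
  clicks$click_correct <- withr::with_seed(config$seed + 2L,
                                           stats::rbinom(nrow(clicks), 1L, p_click))
  clicks$feedback <- truth$feedback[match(clicks$participant_id, truth$participant_id)]
  clicks$task_order <- truth$task_order[match(clicks$participant_id, truth$participant_id)]

  structure(
    list(trials = tibble::as_tibble(clicks), participants = truth,
         schedule = sched, config = config),
    class = "wm_cohort"
  )
}

#' @export
print.wm_cohort <- function(x, ...) {
  cat(sprintf("<wm_cohort> %d participants, %d click-level observations (seed %d)\n",
              nrow(x$participants), nrow(x$trials), x$config$seed))
  cat(sprintf("  mean accuracy %.3f; set sizes %s\n",
              mean(x$trials$click_correct),
              paste(sort(unique(x$trials$set_size)), collapse = ", ")))
  invisible(x)
}

#' Per-participant accuracy on catch trials
#'
#' @param trials Click-level trial table.
#' @return Tibble with `participant_id` and `catch_accuracy` (proportion of
#'   correct clicks on set-size-3 trials).
#' @export
catch_accuracy <- function(trials) {
  trials |>
    dplyr::filter(.data$set_size == 3L) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(catch_accuracy = mean(.data$click_correct), .groups = "drop")
}

# aggregate clicks to one row per participant x trial (identical likelihood)
aggregate_clicks <- function(trials) {
  trials |>
    dplyr::group_by(.data$participant_id, .data$trial_index, .data$set_size) |>
    dplyr::summarise(
      n_clicks = dplyr::n(),
      n_correct = sum(.data$click_correct),
      feedback = .data$feedback[1L],
      task_order = .data$task_order[1L],
      .groups = "drop"
    )
}
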