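#' Plot cohort accuracy over trials
#'
#' Mean observed accuracy per trial across the cohort, colored by set
#' size; the signature footprint of the learning curve and of the set-size
#' psychometric structure.
#'
#' @param object A `wm_cohort`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wm_cohort <- function(object, ...) {
  d <- object$trials |>
    dplyr::group_by(.data$trial_index, .data$set_size) |>
    dplyr::summarise(accuracy = mean(.data$click_correct), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$trial_index, .data$accuracy,
                                  colour = factor(.data$set_size))) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "trial", y = "mean accuracy", colour = "set size") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot fitted trajectories against observed per-trial accuracy
#'
#' @param object A `wm_fit`.
#' @param trials Click-level data the model was fit to.
#' @param participants Participant ids to show (default: up to 6).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wm_fit <- function(object, trials, participants = NULL, ...) {
  est <- extract_estimates(object, trials)
  ids <- participants %||% utils::head(est$participant_id, 6)
  wide <- object$participants |>
    dplyr::select("participant_id", "parameter", "estimate") |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "estimate") |>
    dplyr::filter(.data$participant_id %in% ids)
  pred <- tidyr::crossing(wide, trial_index = 1:68) |>
    dplyr::mutate(accuracy = predict_accuracy(
      .data$trial_index, 6.5,
      list(sigma0 = .data$start, alpha0 = .data$asym, rho = .data$rate,
           sigma_slope = 0, alpha_slope = 0)))
  obs <- trials |>
    dplyr::filter(.data$participant_id %in% ids) |>
    dplyr::group_by(.data$participant_id, .data$trial_index) |>
    dplyr::summarise(accuracy = mean(.data$click_correct), .groups = "drop")
  ggplot2::ggplot(pred, ggplot2::aes(.data$trial_index, .data$accuracy)) +
    ggplot2::geom_point(data = obs, alpha = 0.35, size = 0.8) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::facet_wrap(~participant_id) +
    ggplot2::labs(x = "trial", y = "accuracy") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Forest plot of component--Gf associations
#'
#' @param object A `wm_associations` table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wm_associations <- function(object, ...) {
  d <- dplyr::mutate(object, pair = paste(.data$x, "~", .data$y))
  ggplot2::ggplot(d, ggplot2::aes(.data$estimate, .data$pair)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high)) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("BF[log3] = %.2f", .data$bf_log3)),
                       vjust = -1, size = 3) +
    ggplot2::labs(x = "correlation (bootstrap 95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
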