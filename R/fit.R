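#' Configuration for trajectory model fitting
#'
#' @param mode `"map_fast"` maximizes the penalized joint posterior (same
#'   prior structure, participant deviations given fixed weakly-informative
#'   scales) with an analytic-gradient quasi-Newton optimizer -- the fast
#'   route used for simulation studies and tests. `"full_bayes"` runs a
#'   Gibbs sampler (via JAGS) with hierarchical deviation SDs and reports
#'   convergence diagnostics.
#' @param chains,iter,warmup Sampler budget for `full_bayes`; the reference
#'   budget is 4 chains of 5000 iterations with the first 3000 discarded.
#' @param seed Integer seed for the sampler / optimizer initialization.
#' @param include_catch Include set-size-3 catch trials in the likelihood
#'   (with the same centered set-size covariate). Catch trials always count
#'   toward raw overall accuracy.
#' @param prior_pop_sd,prior_slope_sd,prior_effect_sd Normal prior SDs for
#'   population means, set-size slopes, and condition effects.
#' @param prior_dev_sd Length-3 deviation prior SDs (start, asym, rate) used
#'   by `map_fast`; `full_bayes` instead places half-normal(0, 1) priors on
#'   the deviation SDs.
#' @param max_iter Optimizer iteration cap (`map_fast`).
#' @param se Compute population standard errors from the curvature at the
#'   mode (`map_fast`).
#' @param adapt Adaptation iterations for the JAGS sampler.
#' @return A list of class `wm_fit_config`.
#' @export
fit_config <- function(mode = c("map_fast", "full_bayes"),
                       chains = 4L, iter = 5000L, warmup = 3000L,
                       seed = 1L, include_catch = TRUE,
                       prior_pop_sd = 5, prior_slope_sd = 2, prior_effect_sd = 2,
                       prior_dev_sd = c(start = 1, asym = 1, rate = 1.25),
                       max_iter = 2000L, se = TRUE, adapt = 500L) {
  mode <- match.arg(mode)
  if (iter <= warmup) stop("`iter` must exceed `warmup`.", call. = FALSE)
  if (chains < 1) stop("`chains` must be >= 1.", call. = FALSE)
  structure(
    list(mode = mode, chains = as.integer(chains), iter = as.integer(iter),
         warmup = as.integer(warmup), seed = as.integer(seed),
         include_catch = isTRUE(include_catch),
         prior_pop_sd = prior_pop_sd, prior_slope_sd = prior_slope_sd,
         prior_effect_sd = prior_effect_sd,
         prior_dev_sd = prior_dev_sd, max_iter = as.integer(max_iter),
         se = isTRUE(se), adapt = as.integer(adapt)),
    class = "wm_fit_config"
  )
}

#' Fit the nonlinear mixed-effects trajectory model
#'
#' Fits per-click accuracy as an exponential change over trials with
#' participant random effects on the start, rate and asymptote, population
#' set-size slopes on the start and asymptote predictors, and condition
#' fixed effects (feedback, task order) on all three parameter-level linear
#' predictors. The likelihood is Bernoulli over disaggregated clicks
#' (internally pooled to per-trial binomials, which is the identical
#' likelihood). See [fit_config()] for the two estimation modes.
#'
#' @param trials Click-level data frame (see [curve_loglik()] for required
#'   columns; `feedback` and `task_order` are optional and treated as a
#'   single condition when absent).
#' @param config A [fit_config()].
#' @return An object of class `wm_fit` with elements `population`
#'   (fixed-effect summaries), `participants` (per-participant parameter
#'   summaries on the link scales), `diagnostics`, `click_summary`,
#'   `loglik`, `mode` and `config`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(population_config(n_participants = 8, seed = 3))
#' fit <- fit_trajectories(cohort$trials, fit_config(mode = "map_fast"))
#' tidy(fit)
#' }
#' @export
fit_trajectories <- function(trials, config = fit_config()) {
  stopifnot(inherits(config, "wm_fit_config"))
  if (nrow(trials) == 0L) stop("`trials` is empty.", call. = FALSE)
  if (dplyr::n_distinct(trials$participant_id) < 2L) {
    stop("hierarchical estimation needs >= 2 participants.", call. = FALSE)
  }
  if (!all(trials$click_correct %in% c(0, 1))) {
    stop("`click_correct` must be 0 or 1.", call. = FALSE)
  }
  if (!"feedback" %in% names(trials)) trials$feedback <- "absent"
  if (!"task_order" %in% names(trials)) trials$task_order <- "wm_first"

  click_summary <- trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_clicks = dplyr::n(),
                     n_correct = sum(.data$click_correct), .groups = "drop")

  agg <- aggregate_clicks(trials)
  if (!config$include_catch) agg <- dplyr::filter(agg, .data$set_size != 3L)

  fit <- switch(config$mode,
    map_fast = fit_map_backend(agg, config),
    full_bayes = fit_bayes_backend(agg, config)
  )
  fit$click_summary <- click_summary
  fit$n_participants <- nrow(click_summary)
  fit$config <- config
  fit$seed <- config$seed
  class(fit) <- "wm_fit"
  fit
}

#' @export
print.wm_fit <- function(x, ...) {
  cat(sprintf("<wm_fit> %s fit, %d participants, log-likelihood %.1f\n",
              x$mode, x$n_participants, x$loglik))
  if (x$mode == "full_bayes") {
    cat(sprintf("  max split-Rhat %.3f, min ESS %.0f%s\n",
                x$diagnostics$max_rhat, x$diagnostics$min_ess,
                if (x$diagnostics$max_rhat > 1.05) "  [NOT CONVERGED]" else ""))
  }
  print(x$population)
  invisible(x)
}

#' Extract participant-level point estimates
#'
#' Converts a fitted model into the per-participant components used in
#' individual-differences analysis: `initial_accuracy` and
#' `final_accuracy` are the inverse-logit of the participant start and
#' asymptote predictors at the mean-centered set size (6.5) and average
#' condition; `rate_estimate` stays on the binary log scale (a time
#' constant -- larger is slower); `overall_accuracy` is the raw proportion
#' of correct clicks.
#'
#' @param fit A [fit_trajectories()] result.
#' @param trials Optional click-level table used to recompute raw overall
#'   accuracy; defaults to the click summary stored in the fit. Every
#'   participant in `trials` must be present in the fit.
#' @return Tibble: `participant_id`, `initial_accuracy`, `rate_estimate`,
#'   `final_accuracy`, `overall_accuracy`.
#' @export
extract_estimates <- function(fit, trials = NULL) {
  stopifnot(inherits(fit, "wm_fit"))
  wide <- fit$participants |>
    dplyr::select("participant_id", "parameter", "estimate") |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "estimate")
  if (is.null(trials)) {
    overall <- fit$click_summary |>
      dplyr::mutate(overall_accuracy = .data$n_correct / .data$n_clicks) |>
      dplyr::select("participant_id", "overall_accuracy")
  } else {
    missing <- setdiff(unique(trials$participant_id), wide$participant_id)
    if (length(missing)) {
      stop(sprintf("participant(s) %s not present in fit.",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    overall <- trials |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(overall_accuracy = mean(.data$click_correct), .groups = "drop")
  }
  wide |>
    dplyr::transmute(
      .data$participant_id,
      initial_accuracy = inv_logit(.data$start),
      rate_estimate = .data$rate,
      final_accuracy = inv_logit(.data$asym)
    ) |>
    dplyr::inner_join(overall, by = "participant_id")
}
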