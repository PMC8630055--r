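#' Inverse-logit (logistic) function
#'
#' Maps an unbounded linear predictor to a probability. Start and asymptote
#' parameters live on this scale so that any real-valued predictor implies
#' an accuracy in (0, 1).
#'
#' @param x Numeric vector.
#' @return `1 / (1 + exp(-x))`, numerically stable for large `|x|`.
#' @examples
#' inv_logit(0)
#' @export
inv_logit <- function(x) stats::plogis(x)

#' Rate parameter to time constant
#'
#' The rate of change is estimated on a binary log scale with an additive
#' offset of 2, so the 50%-of-change time constant is `tau = 2^rho + 2`
#' trials. The offset keeps the time constant from taking impossibly small
#' values (tau > 2 always); larger `tau` means slower change.
#'
#' @param rho Numeric vector, rate on the binary log scale.
#' @return Time constant in trials.
#' @examples
#' time_constant(0) # 3 trials
#' @export
time_constant <- function(rho) 2^rho + 2

# linear-predictor clip bound; keeps probabilities strictly inside (0, 1)
ETA_CLIP <- 35

#' Constructor for learning-curve parameters
#'
#' Bundles the parameters of one accuracy trajectory: start and asymptote
#' linear predictors on the logit scale (evaluated at the mean-centered set
#' size of 6.5), the rate on the binary log scale, and population-level
#' set-size slopes in logit units per set-size unit.
#'
#' @param sigma0 Start (initial accuracy) linear predictor, logit scale.
#' @param alpha0 Asymptote (final accuracy) linear predictor, logit scale.
#' @param rho Rate on the binary log scale; time constant is `2^rho + 2`.
#' @param sigma_slope,alpha_slope Set-size slopes for start and asymptote.
#' @return A list of class `wm_curve_params`.
#' @examples
#' curve_params(sigma0 = -0.5, alpha0 = 1.4, rho = 2.6)
#' @export
curve_params <- function(sigma0, alpha0, rho, sigma_slope = 0, alpha_slope = 0) {
  stopifnot(is.numeric(sigma0), is.numeric(alpha0), is.numeric(rho))
  structure(
    list(sigma0 = sigma0, alpha0 = alpha0, rho = rho,
         sigma_slope = sigma_slope, alpha_slope = alpha_slope),
    class = "wm_curve_params"
  )
}

#' Predicted accuracy of the exponential-change trajectory
#'
#' The trajectory moves from the start accuracy S toward the asymptote A as
#' a base-2 exponential in trial number:
#' `p(t) = A + (S - A) * 2^(-(t - 1) / tau)`, with
#' `S = inv_logit(sigma0 + sigma_slope * (set_size - 6.5))`,
#' `A = inv_logit(alpha0 + alpha_slope * (set_size - 6.5))` and
#' `tau = 2^rho + 2`. At trial 1 the prediction is exactly S; at trial
#' `1 + tau` it is exactly halfway between S and A (hence "50%-of-change
#' time constant").
#'
#' @param trial_index Trial number, 1-based.
#' @param set_size Sequence length of the trial.
#' @param params A [curve_params()] object (or list with the same fields).
#' @return Predicted probability of a correct click, in (0, 1).
#' @examples
#' p <- curve_params(sigma0 = -0.5, alpha0 = 1.4, rho = 2.6)
#' predict_accuracy(1:10, 6, p)
#' @export
predict_accuracy <- function(trial_index, set_size, params) {
  if (any(trial_index < 1)) {
    stop("`trial_index` must be >= 1 (trials are 1-based).", call. = FALSE)
  }
  ssc <- set_size - 6.5
  S <- inv_logit(clip_eta(params$sigma0 + params$sigma_slope * ssc))
  A <- inv_logit(clip_eta(params$alpha0 + params$alpha_slope * ssc))
  tau <- time_constant(params$rho)
  A + (S - A) * 2^(-(trial_index - 1) / tau)
}

clip_eta <- function(eta) pmin(pmax(eta, -ETA_CLIP), ETA_CLIP)

#' Bernoulli log-likelihood of click-level data under trajectory parameters
#'
#' Every mouse click is one Bernoulli outcome with success probability given
#' by [predict_accuracy()] for its trial and set size; the log-likelihood is
#' the sum of `y * log(p) + (1 - y) * log(1 - p)` over clicks.
#'
#' @param trials Click-level data frame with columns `participant_id`,
#'   `trial_index`, `set_size` and `click_correct` (0/1).
#' @param params Data frame with one row per participant: `participant_id`,
#'   `sigma0`, `alpha0`, `rho`, and optionally `sigma_slope`/`alpha_slope`
#'   (recycled if absent as 0).
#' @return The summed log-likelihood (0 for empty data).
#' @examples
#' sched <- build_schedule()
#' toy <- tibble::tibble(participant_id = 1, trial_index = 1:3,
#'                       set_size = sched$set_size[1:3], click_correct = c(1, 0, 1))
#' curve_loglik(toy, tibble::tibble(participant_id = 1, sigma0 = 0,
#'                                  alpha0 = 1, rho = 2))
#' @export
curve_loglik <- function(trials, params) {
  if (nrow(trials) == 0L) return(0)
  if (!all(trials$click_correct %in% c(0, 1))) {
    stop("`click_correct` must be 0 or 1.", call. = FALSE)
  }
  if (!all(trials$participant_id %in% params$participant_id)) {
    stop("every observation's participant must have parameters.", call. = FALSE)
  }
  for (col in c("sigma_slope", "alpha_slope")) {
    if (is.null(params[[col]])) params[[col]] <- 0
  }
  if (any(trials$trial_index < 1)) {
    stop("`trial_index` must be >= 1 (trials are 1-based).", call. = FALSE)
  }
  idx <- match(trials$participant_id, params$participant_id)
  ssc <- trials$set_size - 6.5
  # evaluated without the prediction clip so that genuinely saturated
  # parameters surface as an error instead of a silent -Inf
  S <- inv_logit(params$sigma0[idx] + params$sigma_slope[idx] * ssc)
  A <- inv_logit(params$alpha0[idx] + params$alpha_slope[idx] * ssc)
  tau <- time_constant(params$rho[idx])
  p <- A + (S - A) * 2^(-(trials$trial_index - 1) / tau)
  y <- trials$click_correct
  sat <- (p <= 0 & y == 1) | (p >= 1 & y == 0)
  if (any(sat)) {
    stop(sprintf("saturated probability contradicts %d observed click(s); refusing to return -Inf.",
                 sum(sat)), call. = FALSE)
  }
  sum(y * log(p) + (1 - y) * log1p(-p))
}
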