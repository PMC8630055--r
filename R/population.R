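#' Population configuration for synthetic cohorts
#'
#' Describes the generative population the simulator draws from:
#' participant-level start, asymptote (logit scale) and rate (binary log
#' scale) distributions, population set-size slopes, condition fixed
#' effects, and the loadings tying fluid-intelligence (Gf) scores to the
#' asymptote and rate components. The defaults describe a cohort of 87
#' participants whose accuracy begins around 38% at the mean-centered set
#' size, climbs to roughly 80% with a half-change time constant near 8
#' trials, and whose Gf correlates +0.33 with the asymptote and -0.30 with
#' the rate, with no direct path from the start component.
#'
#' With `gf_noise_sd = NULL` the noise standard deviation is set to
#' `sqrt(1 - gf_loading_asym^2 - gf_loading_rate^2)` so the population
#' correlations equal the loadings exactly.
#'
#' @param n_participants Cohort size (>= 2).
#' @param start_mean,start_sd Start logit distribution.
#' @param asym_mean,asym_sd Asymptote logit distribution.
#' @param rate_mean,rate_sd Rate distribution on the binary log scale.
#' @param start_slope,asym_slope Set-size slopes (logit per set-size unit,
#'   negative: larger sequences are harder).
#' @param feedback_effects,order_effects Named numeric vectors
#'   (`start`, `asym`, `rate`) of condition fixed effects on each
#'   parameter's linear predictor (effect-coded conditions, +/- 0.5).
#' @param gf_loading_asym,gf_loading_rate Gf loadings on the standardized
#'   asymptote and rate parameters.
#' @param gf_noise_sd Residual SD of the Gf score, or `NULL` (see above).
#' @param seed Integer seed governing every draw made from this config.
#' @return A list of class `wm_pop_config`.
#' @examples
#' cfg <- population_config(n_participants = 10, seed = 7)
#' @export
population_config <- function(n_participants = 87,
                              start_mean = -0.5, start_sd = 0.75,
                              asym_mean = 1.4, asym_sd = 0.8,
                              rate_mean = 2.6, rate_sd = 1.2,
                              start_slope = -0.35, asym_slope = -0.5,
                              feedback_effects = c(start = 0, asym = 0, rate = 0),
                              order_effects = c(start = 0, asym = 0, rate = 0),
                              gf_loading_asym = 0.33, gf_loading_rate = -0.30,
                              gf_noise_sd = NULL,
                              seed = 1L) {
  if (n_participants < 2) stop("`n_participants` must be >= 2.", call. = FALSE)
  sds <- c(start_sd = start_sd, asym_sd = asym_sd, rate_sd = rate_sd)
  if (any(sds < 0)) stop("parameter SDs must be nonnegative.", call. = FALSE)
  if (is.null(gf_noise_sd)) {
    resid <- 1 - gf_loading_asym^2 - gf_loading_rate^2
    if (resid < 0) stop("Gf loadings imply negative residual variance.", call. = FALSE)
    gf_noise_sd <- sqrt(resid)
  }
  if (gf_noise_sd < 0) stop("`gf_noise_sd` must be nonnegative.", call. = FALSE)
  for (nm in c("feedback_effects", "order_effects")) {
    eff <- get(nm)
    if (!all(c("start", "asym", "rate") %in% names(eff))) {
      stop(sprintf("`%s` must be named with start, asym, rate.", nm), call. = FALSE)
    }
  }
  structure(
    list(n_participants = as.integer(n_participants),
         start_mean = start_mean, start_sd = start_sd,
         asym_mean = asym_mean, asym_sd = asym_sd,
         rate_mean = rate_mean, rate_sd = rate_sd,
         start_slope = start_slope, asym_slope = asym_slope,
         feedback_effects = feedback_effects[c("start", "asym", "rate")],
         order_effects = order_effects[c("start", "asym", "rate")],
         gf_loading_asym = gf_loading_asym, gf_loading_rate = gf_loading_rate,
         gf_noise_sd = gf_noise_sd, seed = as.integer(seed)),
    class = "wm_pop_config"
  )
}

# effect codes: +0.5 / -0.5 so population means sit at the average condition
condition_code <- function(x, positive) ifelse(x == positive, 0.5, -0.5)

#' Draw participant-level trajectory parameters
#'
#' Samples each participant's start, asymptote and rate from independent
#' normal distributions on their link scales, adds the configured condition
#' fixed effects (feedback alternates by participant; task order alternates
#' by pair, mirroring pseudorandom counterbalancing), and returns the truth
#' table the simulator and recovery checks work from.
#'
#' @param config A [population_config()].
#' @return A tibble with columns `participant_id`, `feedback`,
#'   `task_order`, `sigma0`, `alpha0`, `rho`.
#' @examples
#' sample_population_params(population_config(n_participants = 4))
#' @export
sample_population_params <- function(config) {
  stopifnot(inherits(config, "wm_pop_config"))
  n <- config$n_participants
  id <- seq_len(n)
  feedback <- ifelse(id %% 2L == 1L, "present", "absent")
  task_order <- ifelse(((id - 1L) %/% 2L) %% 2L == 0L, "wm_first", "gf_first")
  fb <- condition_code(feedback, "present")
  or <- condition_code(task_order, "wm_first")
  withr::with_seed(config$seed, {
    tibble::tibble(
      participant_id = id,
      feedback = feedback,
      task_order = task_order,
      sigma0 = stats::rnorm(n, config$start_mean, config$start_sd) +
        config$feedback_effects[["start"]] * fb + config$order_effects[["start"]] * or,
      alpha0 = stats::rnorm(n, config$asym_mean, config$asym_sd) +
        config$feedback_effects[["asym"]] * fb + config$order_effects[["asym"]] * or,
      rho = stats::rnorm(n, config$rate_mean, config$rate_sd) +
        config$feedback_effects[["rate"]] * fb + config$order_effects[["rate"]] * or
    )
  })
}

#' Generate Gf scores linked to trajectory components
#'
#' Builds each participant's fluid-intelligence score from the standardized
#' asymptote and rate parameters plus independent noise,
#' `gf = b_asym * z(alpha0) + b_rate * z(rho) + e`, then standardizes over
#' the cohort. There is deliberately no term in the start parameter: the
#' generative population carries links from final accuracy and rate of
#' change only. Standardization uses the configured population moments, so
#' with the default noise SD the population correlations equal the loadings.
#'
#' @param params Truth table from [sample_population_params()].
#' @param config The same [population_config()].
#' @return `params` with a `gf` column appended.
#' @examples
#' cfg <- population_config(n_participants = 20)
#' generate_gf(sample_population_params(cfg), cfg)
#' @export
generate_gf <- function(params, config) {
  stopifnot(inherits(config, "wm_pop_config"))
  if (nrow(params) == 0L) stop("parameter table is empty.", call. = FALSE)
  z <- function(x, mu, sd) if (sd > 0) (x - mu) / sd else rep(0, length(x))
  raw <- withr::with_seed(config$seed + 1L,
    config$gf_loading_asym * z(params$alpha0, config$asym_mean, config$asym_sd) +
      config$gf_loading_rate * z(params$rho, config$rate_mean, config$rate_sd) +
      stats::rnorm(nrow(params), 0, config$gf_noise_sd)
  )
  s <- stats::sd(raw)
  params$gf <- if (is.na(s) || s == 0) rep(0, length(raw)) else (raw - mean(raw)) / s
  params
}
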