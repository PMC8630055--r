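#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted trajectory model
#'
#' @param x A `wm_fit`.
#' @param effects `"population"` for fixed effects (and, for full-Bayes
#'   fits, deviation SDs), `"participants"` for participant-level parameter
#'   summaries on the link scales.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.wm_fit <- function(x, effects = c("population", "participants"), ...) {
  effects <- match.arg(effects)
  if (effects == "population") x$population else x$participants
}

#' One-row summary of a fitted trajectory model
#'
#' @param x A `wm_fit`.
#' @param ... Unused.
#' @return Tibble with `mode`, `n_participants`, `loglik`, `max_rhat`
#'   (NA for the optimizer mode), `min_ess` and `converged`.
#' @export
glance.wm_fit <- function(x, ...) {
  if (x$mode == "full_bayes") {
    tibble::tibble(mode = x$mode, n_participants = x$n_participants,
                   loglik = x$loglik, max_rhat = x$diagnostics$max_rhat,
                   min_ess = x$diagnostics$min_ess,
                   converged = x$diagnostics$max_rhat <= 1.05)
  } else {
    tibble::tibble(mode = x$mode, n_participants = x$n_participants,
                   loglik = x$loglik, max_rhat = NA_real_, min_ess = NA_real_,
                   converged = x$diagnostics$convergence == 0)
  }
}

#' @export
tidy.wm_regression <- function(x, ...) x$coefficients

#' @export
glance.wm_regression <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n = x$n,
                 sigma = summary(x$fit)$sigma)
}
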