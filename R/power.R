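#' Power to detect a correlation (Fisher-z approximation)
#'
#' Two-sided rejection probability under the Fisher-z approximation,
#' `Phi(|z_r| * sqrt(n - 3) - z_(1 - alpha/2)) +
#'  Phi(-|z_r| * sqrt(n - 3) - z_(1 - alpha/2))` with `z_r = atanh(r)`.
#' The second (far-tail) term is negligible for any practically detectable
#' effect but makes the null case exact: at `r = 0` the power equals
#' `alpha`.
#'
#' @param n Sample size (>= 4).
#' @param r Population correlation, `|r| < 1`.
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1).
#' @examples
#' power_at(87, 0.295)
#' @export
power_at <- function(n, r, alpha = 0.05) {
  if (n < 4) stop("need n >= 4.", call. = FALSE)
  if (abs(r) >= 1) stop("`r` must satisfy |r| < 1.", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1).", call. = FALSE)
  zcrit <- stats::qnorm(1 - alpha / 2)
  za <- abs(atanh(r)) * sqrt(n - 3)
  stats::pnorm(za - zcrit) + stats::pnorm(-za - zcrit)
}

#' Minimum detectable correlation at a target power
#'
#' Inverts the Fisher-z power approximation:
#' `r = tanh((z_(1 - alpha/2) + z_power) / sqrt(n - 3))`.
#'
#' @param n Sample size (>= 4).
#' @param power Target power in (0, 1).
#' @param alpha Two-sided significance level.
#' @return The smallest population correlation detectable with the target
#'   power.
#' @examples
#' min_detectable_r(87, 0.80, 0.05)
#' @export
min_detectable_r <- function(n, power = 0.80, alpha = 0.05) {
  if (n < 4) stop("need n >= 4.", call. = FALSE)
  if (power <= 0 || power >= 1 || alpha <= 0 || alpha >= 1) {
    stop("`power` and `alpha` must be in (0, 1).", call. = FALSE)
  }
  tanh((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / sqrt(n - 3))
}
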