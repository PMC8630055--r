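#' Fluid-intelligence composite score
#'
#' Z-scores percent correct on each matrix-reasoning task independently
#' over the cohort, then averages the two z-scores per participant.
#'
#' @param task1_pct,task2_pct Percent-correct vectors, same length >= 2 and
#'   nonconstant.
#' @param participant_id Optional ids (defaults to position).
#' @return Tibble: `participant_id`, `task1_pct`, `task2_pct`, `composite`.
#' @examples
#' gf_composite(c(40, 60, 55), c(50, 70, 58))
#' @export
gf_composite <- function(task1_pct, task2_pct, participant_id = seq_along(task1_pct)) {
  if (length(task1_pct) != length(task2_pct)) {
    stop("task score vectors must have equal length.", call. = FALSE)
  }
  if (length(task1_pct) < 2) stop("need at least two participants.", call. = FALSE)
  if (stats::sd(task1_pct) == 0 || stats::sd(task2_pct) == 0) {
    stop("degenerate variance: a task score vector is constant.", call. = FALSE)
  }
  z <- function(x) (x - mean(x)) / stats::sd(x)
  tibble::tibble(
    participant_id = participant_id,
    task1_pct = task1_pct, task2_pct = task2_pct,
    composite = (z(task1_pct) + z(task2_pct)) / 2
  )
}

#' Correlation with bootstrap confidence interval
#'
#' Pearson (or Spearman) correlation with a seeded percentile bootstrap
#' interval over paired resamples of `(x, y)` rows.
#'
#' @param x,y Numeric vectors, equal length `n >= 4`, finite, nonconstant.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Integer seed for resampling.
#' @param method `"pearson"` or `"spearman"`.
#' @param conf Interval coverage (default 0.95).
#' @return One-row tibble: `method`, `estimate`, `ci_low`, `ci_high`, `n`,
#'   `n_boot`, `seed`.
#' @examples
#' correlation_with_ci(rnorm(20), rnorm(20), n_boot = 200, seed = 1)
#' @export
correlation_with_ci <- function(x, y, n_boot = 10000L, seed = 1L,
                                method = c("pearson", "spearman"), conf = 0.95) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length.", call. = FALSE)
  n <- length(x)
  if (n < 4) stop("need n >= 4 observations.", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("inputs must be finite.", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate variance: an input vector is constant.", call. = FALSE)
  }
  est <- stats::cor(x, y, method = method)
  boot <- withr::with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    if (method == "pearson") {
      xb <- matrix(x[idx], nrow = n); yb <- matrix(y[idx], nrow = n)
      cx <- xb - rep(colMeans(xb), each = n)
      cy <- yb - rep(colMeans(yb), each = n)
      colSums(cx * cy) / sqrt(colSums(cx^2) * colSums(cy^2))
    } else {
      apply(idx, 2, function(i) suppressWarnings(stats::cor(x[i], y[i], method = "spearman")))
    }
  })
  qs <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  tibble::tibble(method = method, estimate = est,
                 ci_low = unname(qs[1]), ci_high = unname(qs[2]),
                 n = n, n_boot = as.integer(n_boot), seed = as.integer(seed))
}

#' Default-prior Bayes factor for a correlation, log base 3
#'
#' Computes the Bayes factor for H1 (nonzero population correlation, with a
#' stretched-beta prior of width `prior_width` on the correlation) against
#' H0 (zero correlation), by numerical integration of the reduced
#' likelihood of the observed Pearson r in log space. Returned on the
#' log-base-3 scale, so +1 and -1 mark the conventional 3:1 evidence
#' thresholds for H1 and H0.
#'
#' @param r Observed Pearson correlation, `|r| < 1`.
#' @param n Sample size (>= 4).
#' @param prior_width Stretched-beta scale; 1/3 is the conventional
#'   "medium" default (the prior is Beta(1/width, 1/width) stretched to
#'   (-1, 1); width 1 gives the uniform prior).
#' @return `log3` of the Bayes factor (positive favors a nonzero
#'   correlation).
#' @examples
#' correlation_bf_log3(0.33, 87)
#' @export
correlation_bf_log3 <- function(r, n, prior_width = 1 / 3) {
  if (abs(r) >= 1) stop("`r` must satisfy |r| < 1.", call. = FALSE)
  if (n < 4) stop("need n >= 4.", call. = FALSE)
  if (prior_width <= 0) stop("`prior_width` must be positive.", call. = FALSE)
  a <- 1 / prior_width
  log_g <- function(rho) {
    (n - 1) / 2 * log1p(-rho^2) - (n - 3 / 2) * log1p(-rho * r) +
      vapply(rho, function(p) log_hyp2f1_half(n, (1 + p * r) / 2), 0)
  }
  log_g0 <- log_g(0)
  num <- tryCatch(
    stats::integrate(function(rho) exp(log_g(rho) - log_g0) * (1 - rho^2)^(a - 1),
                     -1, 1, rel.tol = 1e-9),
    error = function(e) stop("Bayes factor integration failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  den <- stats::integrate(function(rho) (1 - rho^2)^(a - 1), -1, 1, rel.tol = 1e-9)
  (log(num$value) - log(den$value)) / log(3)
}

# log of 2F1(1/2, 1/2; n - 1/2; z) by series; z in [0, 1) here and the
# series terms decay geometrically for the arguments this model produces
log_hyp2f1_half <- function(n, z, tol = 1e-13, maxit = 10000L) {
  term <- 1; s <- 1
  cpar <- n - 0.5
  for (k in 0:maxit) {
    term <- term * (0.5 + k)^2 / ((cpar + k) * (k + 1)) * z
    s <- s + term
    if (abs(term) < tol * abs(s)) return(log(s))
  }
  stop("hypergeometric series did not converge.", call. = FALSE)
}

#' Associate trajectory components with Gf
#'
#' The individual-differences layer: correlates each extracted trajectory
#' component (initial, rate, final, overall accuracy) with the Gf score,
#' and overall accuracy with final accuracy and with rate, reporting the
#' bootstrap interval and the default-prior log-base-3 Bayes factor for
#' each pair.
#'
#' @param estimates Tibble from [extract_estimates()].
#' @param gf Tibble with `participant_id` and `gf` (or a `composite` column
#'   from [gf_composite()]).
#' @param n_boot,seed,method,prior_width Passed to [correlation_with_ci()]
#'   and [correlation_bf_log3()].
#' @return Tibble of class `wm_associations`, one row per pair: `x`, `y`,
#'   `method`, `estimate`, `ci_low`, `ci_high`, `bf_log3`, `n`.
#' @export
associate_components <- function(estimates, gf, n_boot = 10000L, seed = 1L,
                                 method = "pearson", prior_width = 1 / 3) {
  if ("composite" %in% names(gf) && !"gf" %in% names(gf)) gf$gf <- gf$composite
  dat <- dplyr::inner_join(estimates, gf[, c("participant_id", "gf")],
                           by = "participant_id")
  pairs <- list(
    c("initial_accuracy", "gf"), c("rate_estimate", "gf"),
    c("final_accuracy", "gf"), c("overall_accuracy", "gf"),
    c("overall_accuracy", "final_accuracy"), c("rate_estimate", "overall_accuracy")
  )
  res <- purrr::map_dfr(pairs, function(pr) {
    ci <- correlation_with_ci(dat[[pr[1]]], dat[[pr[2]]], n_boot = n_boot,
                              seed = seed, method = method)
    tibble::tibble(x = pr[1], y = pr[2], method = ci$method, estimate = ci$estimate,
                   ci_low = ci$ci_low, ci_high = ci$ci_high,
                   bf_log3 = correlation_bf_log3(stats::cor(dat[[pr[1]]], dat[[pr[2]]]),
                                                 nrow(dat), prior_width),
                   n = nrow(dat))
  })
  class(res) <- c("wm_associations", class(res))
  res
}
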