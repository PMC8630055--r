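test_that("inverse logit satisfies the logistic identities", {
  expect_equal(inv_logit(0), 0.5)
  x <- c(-3.2, -0.7, 0.4, 2.9, 12)
  expect_equal(inv_logit(x) + inv_logit(-x), rep(1, length(x)))
  expect_lt(abs(inv_logit(40) - 1), 1e-12)
  expect_true(is.finite(inv_logit(700)) && is.finite(inv_logit(-700)))
})

test_that("time constant is the offset binary power", {
  expect_equal(time_constant(0), 3)
  expect_equal(time_constant(3), 10)
  expect_gt(time_constant(-50), 2)           # bounded below by the offset
  expect_equal(time_constant(-1e4), 2)       # limit reached only numerically
})

test_that("trajectory hits its anchor points exactly", {
  p <- curve_params(sigma0 = -0.8, alpha0 = 1.6, rho = 2.2,
                    sigma_slope = -0.35, alpha_slope = -0.5)
  for (ss in c(3, 5, 6, 7, 8)) {
    S <- inv_logit(p$sigma0 + p$sigma_slope * (ss - 6.5))
    A <- inv_logit(p$alpha0 + p$alpha_slope * (ss - 6.5))
    tau <- time_constant(p$rho)
    expect_equal(predict_accuracy(1, ss, p), S)
    expect_equal(predict_accuracy(1 + tau, ss, p), (S + A) / 2)
    expect_lt(abs(predict_accuracy(1 + 30 * tau, ss, p) - A), 1e-9)
  }
})

test_that("stationary and monotone regimes behave as the form dictates", {
  flat <- curve_params(sigma0 = 0.7, alpha0 = 0.7, rho = 1)
  expect_equal(predict_accuracy(c(1, 5, 40), 6.5, flat),
               rep(inv_logit(0.7), 3))
  t <- 1:68
  rising <- predict_accuracy(t, 6.5, curve_params(-1, 2, 2.5))
  falling <- predict_accuracy(t, 6.5, curve_params(2, -1, 2.5))
  expect_true(all(diff(rising) > 0))
  expect_true(all(diff(falling) < 0))
  # bounded in (0, 1) across a parameter sweep
  set.seed(7)
  for (i in 1:50) {
    pp <- curve_params(rnorm(1, 0, 5), rnorm(1, 0, 5), rnorm(1, 0, 3),
                       rnorm(1, 0, 1), rnorm(1, 0, 1))
    pr <- predict_accuracy(t, sample(c(3, 5, 6, 7, 8), 1), pp)
    expect_true(all(pr > 0 & pr < 1))
  }
  expect_error(predict_accuracy(0, 6, flat), "1-based")
})

test_that("log-likelihood matches closed form and brute force", {
  co <- tiny_cohort(n = 2, seed = 9)
  params <- co$participants[, c("participant_id", "sigma0", "alpha0", "rho")]
  params$sigma_slope <- co$config$start_slope
  params$alpha_slope <- co$config$asym_slope

  # p = 0.5 everywhere: sigma0 = alpha0 = 0 with zero slopes
  half <- params
  half$sigma0 <- 0; half$alpha0 <- 0; half$sigma_slope <- 0; half$alpha_slope <- 0
  one <- co$trials[co$trials$participant_id == 1, ]
  expect_equal(curve_loglik(one, half), nrow(one) * log(0.5))
  expect_equal(nrow(one), 428)

  expect_equal(curve_loglik(co$trials[0, ], params), 0)

  set.seed(11)
  small <- co$trials[sample(nrow(co$trials), 50), ]
  expect_equal(curve_loglik(small, params), brute_force_loglik(small, params),
               tolerance = 1e-10)
  # and on a second draw with different parameters
  params2 <- params
  params2$rho <- params2$rho + 0.8
  small2 <- co$trials[1:37, ]
  expect_equal(curve_loglik(small2, params2), brute_force_loglik(small2, params2),
               tolerance = 1e-10)
})

test_that("log-likelihood refuses saturated contradictions and orphans", {
  toy <- tibble::tibble(participant_id = 1, trial_index = 1, set_size = 6,
                        click_correct = 1)
  sat <- tibble::tibble(participant_id = 1, sigma0 = -800, alpha0 = -800, rho = 0)
  expect_error(curve_loglik(toy, sat), "satur")
  expect_error(
    curve_loglik(tibble::tibble(participant_id = 2, trial_index = 1,
                                set_size = 6, click_correct = 1),
                 sat),
    "parameters")
})
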