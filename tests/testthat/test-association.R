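test_that("Gf composite is the mean of within-task z-scores", {
  g <- gf_composite(c(40, 60), c(50, 70))
  # hand computation: both tasks z to (-sqrt(2)/2, +sqrt(2)/2)
  expect_equal(g$composite, c(-sqrt(2) / 2, sqrt(2) / 2))

  t1 <- c(30, 45, 62, 81, 55)
  same <- gf_composite(t1, t1)
  expect_equal(same$composite, (t1 - mean(t1)) / sd(t1))

  set.seed(1)
  big <- gf_composite(runif(87, 20, 95), runif(87, 20, 95))
  expect_lt(abs(mean(big$composite)), 1e-12)

  expect_error(gf_composite(rep(50, 4), c(1, 2, 3, 4)), "degenerate")
  expect_error(gf_composite(1:3, 1:4), "equal length")
})

test_that("bootstrap correlation intervals behave at the extremes and the null", {
  x <- c(0.3, 1.2, -0.5, 2.2, 0.9, -1.4)
  perfect <- correlation_with_ci(x, x, n_boot = 500, seed = 3)
  expect_equal(perfect$estimate, 1)
  expect_equal(perfect$ci_low, 1)
  expect_equal(perfect$ci_high, 1)
  expect_equal(correlation_with_ci(x, -x, n_boot = 100, seed = 3)$estimate, -1)

  set.seed(8)
  xn <- rnorm(5000); yn <- rnorm(5000)
  nul <- correlation_with_ci(xn, yn, n_boot = 400, seed = 5)
  expect_lt(abs(nul$estimate), 0.05)
  expect_true(nul$ci_low < 0 && nul$ci_high > 0)

  expect_identical(correlation_with_ci(x, rev(x), n_boot = 200, seed = 9),
                   correlation_with_ci(x, rev(x), n_boot = 200, seed = 9))
  expect_error(correlation_with_ci(x, rep(1, 6)), "degenerate")
  expect_error(correlation_with_ci(x[1:3], x[1:3]), "n >= 4")

  sp <- correlation_with_ci(x, x^3, n_boot = 100, seed = 2, method = "spearman")
  expect_equal(sp$estimate, 1)  # monotone map preserves ranks
})

test_that("bootstrap interval coverage is near nominal", {
  # known bivariate normal population, rho = 0.4
  rho <- 0.4
  hits <- vapply(1:400, function(s) {
    withr::with_seed(1e6 + s, {
      x <- rnorm(87)
      y <- rho * x + sqrt(1 - rho^2) * rnorm(87)
    })
    ci <- correlation_with_ci(x, y, n_boot = 600, seed = s)
    ci$ci_low <= rho && rho <= ci$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.92)
  expect_lte(mean(hits), 0.97)
})

test_that("correlation Bayes factor matches an independent closed form", {
  grid <- expand.grid(r = c(0, 0.1, -0.25, 0.33, -0.6, 0.9), n = c(10, 40, 87))
  for (i in seq_len(nrow(grid))) {
    expect_equal(correlation_bf_log3(grid$r[i], grid$n[i]),
                 closed_form_bf_log3(abs(grid$r[i]), grid$n[i]),
                 tolerance = 1e-6,
                 info = sprintf("r=%.2f n=%d", grid$r[i], grid$n[i]))
  }
  # and for other prior widths
  expect_equal(correlation_bf_log3(0.33, 87, prior_width = 1),
               closed_form_bf_log3(0.33, 87, kappa = 1), tolerance = 1e-6)
})

test_that("Bayes factor is even in r and monotone in |r| and n", {
  expect_equal(correlation_bf_log3(0.4, 60), correlation_bf_log3(-0.4, 60))
  rs <- seq(0.05, 0.9, by = 0.05)
  bfs <- vapply(rs, correlation_bf_log3, 0, n = 87)
  expect_true(all(diff(bfs) > 0))
  ns <- c(10, 20, 40, 87, 200)
  bfn <- vapply(ns, function(n) correlation_bf_log3(0.3, n), 0)
  expect_true(all(diff(bfn) > 0))
  expect_lt(correlation_bf_log3(0, 87), 0)
  expect_error(correlation_bf_log3(1, 87), "\\|r\\|")
})

test_that("component association table carries estimates, CIs and BFs", {
  co <- tiny_cohort(n = 20, seed = 31)
  fit <- fit_trajectories(co$trials, fit_config(mode = "map_fast", se = FALSE))
  est <- extract_estimates(fit)
  assoc <- associate_components(est, co$participants[, c("participant_id", "gf")],
                                n_boot = 300, seed = 4)
  expect_equal(nrow(assoc), 6)
  expect_true(all(assoc$ci_low <= assoc$estimate & assoc$estimate <= assoc$ci_high))
  expect_true(all(is.finite(assoc$bf_log3)))
  expect_equal(unique(assoc$n), 20)
  # composite column is accepted in place of a gf column
  gf2 <- tibble::tibble(participant_id = co$participants$participant_id,
                        composite = co$participants$gf)
  assoc2 <- associate_components(est, gf2, n_boot = 300, seed = 4)
  expect_equal(assoc2$estimate, assoc$estimate)
})
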