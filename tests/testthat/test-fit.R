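test_that("fit configuration enforces sampler budget sanity", {
  expect_error(fit_config(iter = 100, warmup = 100), "exceed")
  expect_error(fit_config(chains = 0), "chains")
  expect_equal(fit_config()$iter, 5000L)
  expect_equal(fit_config()$warmup, 3000L)
  expect_equal(fit_config()$chains, 4L)
})

test_that("fitting requires a cohort, not a single participant", {
  co <- tiny_cohort(n = 2, seed = 1)
  solo <- co$trials[co$trials$participant_id == 1, ]
  expect_error(fit_trajectories(solo, fit_config()), ">= 2 participants")
  expect_error(fit_trajectories(co$trials[0, ], fit_config()), "empty")
})

test_that("map_fast recovers the population structure of a mid-sized cohort", {
  co <- simulate_cohort(population_config(n_participants = 30, seed = 14))
  fit <- fit_trajectories(co$trials, fit_config(mode = "map_fast", seed = 1))
  expect_s3_class(fit, "wm_fit")
  expect_equal(nrow(fit$participants), 3 * 30)

  est <- extract_estimates(fit)
  truth <- co$participants
  expect_true(all(est$initial_accuracy > 0 & est$initial_accuracy < 1))
  expect_true(all(est$final_accuracy > 0 & est$final_accuracy < 1))
  expect_gt(cor(est$final_accuracy, inv_logit(truth$alpha0)), 0.85)
  expect_gt(cor(est$initial_accuracy, inv_logit(truth$sigma0)), 0.6)
  expect_gt(cor(est$rate_estimate, truth$rho), 0.5)
  # population set-size slopes recovered with the right sign and rough size
  pop <- tidy(fit)
  expect_lt(pop$estimate[pop$term == "asym_slope"], -0.2)
  expect_lt(pop$estimate[pop$term == "start_slope"], 0)
})

test_that("a null feedback effect is estimated near zero with covering interval", {
  co <- simulate_cohort(population_config(n_participants = 40, seed = 23))
  fit <- fit_trajectories(co$trials, fit_config(mode = "map_fast", seed = 2))
  pop <- tidy(fit)
  for (term in c("feedback_start", "feedback_asym", "feedback_rate")) {
    row <- pop[pop$term == term, ]
    expect_true(row$ci_low < 0 && row$ci_high > 0)
  }
})

test_that("hierarchical shrinkage compresses homogeneous cohorts", {
  homog <- simulate_cohort(population_config(n_participants = 15, seed = 8,
                                             start_sd = 0, asym_sd = 0, rate_sd = 0))
  heterog <- simulate_cohort(population_config(n_participants = 15, seed = 8))
  f1 <- fit_trajectories(homog$trials, fit_config(mode = "map_fast", se = FALSE))
  f2 <- fit_trajectories(heterog$trials, fit_config(mode = "map_fast", se = FALSE))
  spread <- function(f, par) sd(f$participants$estimate[f$participants$parameter == par])
  for (par in c("start", "asym", "rate")) {
    expect_lt(spread(f1, par), spread(f2, par))
  }
})

test_that("full-Bayes and map_fast point estimates agree in rank", {
  co <- simulate_cohort(population_config(n_participants = 30, seed = 4))
  cfg_b <- fit_config(mode = "full_bayes", chains = 2, iter = 900, warmup = 300,
                      adapt = 300, seed = 10)
  # a short sampling budget may legitimately warn about convergence;
  # the diagnostics below assert it is reported either way
  fb <- suppressWarnings(fit_trajectories(co$trials, cfg_b))
  fm <- fit_trajectories(co$trials, fit_config(mode = "map_fast", seed = 10, se = FALSE))
  eb <- extract_estimates(fb)
  em <- extract_estimates(fm)
  expect_equal(eb$participant_id, em$participant_id)
  for (col in c("initial_accuracy", "rate_estimate", "final_accuracy")) {
    expect_gte(cor(eb[[col]], em[[col]], method = "spearman"), 0.9)
  }
  # diagnostics are reported for every monitored quantity
  expect_true(all(is.finite(fb$diagnostics$summary$rhat)))
  expect_true(is.finite(fb$diagnostics$max_rhat))
  g <- glance(fb)
  expect_equal(g$mode, "full_bayes")
})

test_that("extracted estimates expose raw overall accuracy and demand consistency", {
  co <- tiny_cohort(n = 3, seed = 16)
  fit <- fit_trajectories(co$trials, fit_config(mode = "map_fast", se = FALSE))
  est <- extract_estimates(fit, co$trials)
  manual <- tapply(co$trials$click_correct, co$trials$participant_id, mean)
  expect_equal(est$overall_accuracy, as.numeric(manual[as.character(est$participant_id)]))

  stranger <- co$trials
  stranger$participant_id <- stranger$participant_id + 100
  expect_error(extract_estimates(fit, stranger), "not present in fit")
})

test_that("asymptote ordering survives fitting for distinct participant types", {
  cfg <- population_config(n_participants = 10, seed = 6,
                           asym_sd = 0, start_sd = 0, rate_sd = 0)
  co <- simulate_cohort(cfg)
  # plant two types: half high asymptote, half low
  truth <- co$participants
  truth$alpha0 <- ifelse(truth$participant_id %% 2 == 0, 2.2, 0.4)
  per <- tidyr::crossing(participant_id = truth$participant_id,
                         co$schedule[, c("trial_index", "set_size")])
  idx <- match(per$participant_id, truth$participant_id)
  p <- predict_accuracy(per$trial_index, per$set_size,
                        list(sigma0 = truth$sigma0[idx], alpha0 = truth$alpha0[idx],
                             rho = truth$rho[idx], sigma_slope = cfg$start_slope,
                             alpha_slope = cfg$asym_slope))
  clicks <- per[rep(seq_len(nrow(per)), per$set_size), ]
  set.seed(99)
  clicks$click_correct <- rbinom(nrow(clicks), 1, rep(p, per$set_size))
  fit <- fit_trajectories(clicks, fit_config(mode = "map_fast", se = FALSE))
  est <- extract_estimates(fit)
  hi <- est$final_accuracy[est$participant_id %% 2 == 0]
  lo <- est$final_accuracy[est$participant_id %% 2 == 1]
  expect_gt(min(hi), max(lo))
})
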