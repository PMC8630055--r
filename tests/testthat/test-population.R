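test_that("population config validates its inputs", {
  expect_error(population_config(n_participants = 1), ">= 2")
  expect_error(population_config(start_sd = -0.1), "nonnegative")
  expect_error(population_config(gf_noise_sd = -1), "nonnegative")
  expect_error(population_config(gf_loading_asym = 0.9, gf_loading_rate = 0.9),
               "residual variance")
  # default noise SD completes the loadings to unit variance
  cfg <- population_config()
  expect_equal(cfg$gf_noise_sd, sqrt(1 - 0.33^2 - 0.30^2))
})

test_that("parameter draws are reproducible and respect degenerate SDs", {
  cfg <- population_config(n_participants = 12, seed = 31)
  expect_identical(sample_population_params(cfg), sample_population_params(cfg))

  frozen <- population_config(n_participants = 8, start_sd = 0, asym_sd = 0,
                              rate_sd = 0, seed = 3)
  p <- sample_population_params(frozen)
  expect_equal(p$sigma0, rep(frozen$start_mean, 8))
  expect_equal(p$alpha0, rep(frozen$asym_mean, 8))
  expect_equal(p$rho, rep(frozen$rate_mean, 8))
})

test_that("draw moments match the configured population", {
  cfg <- population_config(n_participants = 10000, seed = 4)
  p <- sample_population_params(cfg)
  for (pair in list(c("sigma0", "start"), c("alpha0", "asym"), c("rho", "rate"))) {
    mu <- cfg[[paste0(pair[2], "_mean")]]
    sd <- cfg[[paste0(pair[2], "_sd")]]
    expect_lt(abs(mean(p[[pair[1]]]) - mu), 3 * sd / sqrt(10000))
  }
})

test_that("condition labels are balanced and effects shift the right parameter", {
  cfg <- population_config(n_participants = 40, seed = 5,
                           feedback_effects = c(start = 0, asym = 1, rate = 0))
  p <- sample_population_params(cfg)
  expect_equal(sum(p$feedback == "present"), 20)
  expect_equal(sum(p$task_order == "wm_first"), 20)
  # +1 on the asymptote under effect coding = 1.0 gap between conditions
  cfg0 <- population_config(n_participants = 40, seed = 5)
  p0 <- sample_population_params(cfg0)
  gap <- mean(p$alpha0[p$feedback == "present"]) - mean(p$alpha0[p$feedback == "absent"])
  gap0 <- mean(p0$alpha0[p0$feedback == "present"]) - mean(p0$alpha0[p0$feedback == "absent"])
  expect_equal(gap - gap0, 1.0, tolerance = 1e-10)
})

test_that("null and deterministic Gf configurations behave exactly", {
  null_cfg <- population_config(n_participants = 4000, seed = 6,
                                gf_loading_asym = 0, gf_loading_rate = 0,
                                gf_noise_sd = 1)
  p <- generate_gf(sample_population_params(null_cfg), null_cfg)
  expect_lt(abs(cor(p$gf, p$sigma0)), 0.05)
  expect_lt(abs(cor(p$gf, p$alpha0)), 0.05)
  expect_lt(abs(cor(p$gf, p$rho)), 0.05)

  det_cfg <- population_config(n_participants = 50, seed = 7,
                               gf_loading_asym = 1, gf_loading_rate = 0,
                               gf_noise_sd = 0)
  pd <- generate_gf(sample_population_params(det_cfg), det_cfg)
  expect_equal(cor(pd$gf, pd$alpha0), 1)
})

test_that("default loadings are calibrated to the target population links", {
  # Monte-Carlo calibration: mean sample correlations over replicate cohorts
  rs <- vapply(1:500, function(s) {
    cfg <- population_config(seed = s)
    p <- generate_gf(sample_population_params(cfg), cfg)
    c(cor(p$alpha0, p$gf), cor(p$rho, p$gf))
  }, numeric(2))
  expect_lt(abs(mean(rs[1, ]) - 0.33), 0.03)
  expect_lt(abs(mean(rs[2, ]) - (-0.30)), 0.03)
})

test_that("Gf carries no partial association with the start component", {
  cfg <- population_config(n_participants = 10000, seed = 8)
  p <- generate_gf(sample_population_params(cfg), cfg)
  res_gf <- resid(lm(gf ~ alpha0 + rho, data = p))
  res_s <- resid(lm(sigma0 ~ alpha0 + rho, data = p))
  expect_lt(abs(cor(res_gf, res_s)), 0.03)
})

test_that("generate_gf rejects an empty table", {
  cfg <- population_config()
  expect_error(generate_gf(sample_population_params(cfg)[0, ], cfg), "empty")
})
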