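# Full-Bayes backend: hierarchical model sampled with JAGS. Deviation SDs
# get half-normal(0, 1) priors; population means N(0, 5), slopes and
# condition effects N(0, 2) by default (config scales). The likelihood is
# the same per-trial binomial pooling used by the optimizer.

jags_model_string <- function(config) {
  sprintf("
model {
  for (i in 1:N) {
    etaS[i] <- muS + uS[pid[i]] + slS*ssc[i] + fbS*fb[i] + orS*orc[i]
    etaA[i] <- muA + uA[pid[i]] + slA*ssc[i] + fbA*fb[i] + orA*orc[i]
    tauc[i] <- pow(2, muR + uR[pid[i]] + fbR*fb[i] + orR*orc[i]) + 2
    p[i] <- ilogit(etaA[i]) + (ilogit(etaS[i]) - ilogit(etaA[i])) * pow(2, -(t[i]-1)/tauc[i])
    y[i] ~ dbin(p[i], m[i])
  }
  for (j in 1:J) {
    uS[j] ~ dnorm(0, precS)
    uA[j] ~ dnorm(0, precA)
    uR[j] ~ dnorm(0, precR)
  }
  muS ~ dnorm(0, %g); muA ~ dnorm(0, %g); muR ~ dnorm(0, %g)
  slS ~ dnorm(0, %g); slA ~ dnorm(0, %g)
  fbS ~ dnorm(0, %g); fbA ~ dnorm(0, %g); fbR ~ dnorm(0, %g)
  orS ~ dnorm(0, %g); orA ~ dnorm(0, %g); orR ~ dnorm(0, %g)
  sdS ~ dnorm(0, 1) T(0,); sdA ~ dnorm(0, 1) T(0,); sdR ~ dnorm(0, 1) T(0,)
  precS <- pow(sdS, -2); precA <- pow(sdA, -2); precR <- pow(sdR, -2)
}",
    config$prior_pop_sd^-2, config$prior_pop_sd^-2, config$prior_pop_sd^-2,
    config$prior_slope_sd^-2, config$prior_slope_sd^-2,
    config$prior_effect_sd^-2, config$prior_effect_sd^-2, config$prior_effect_sd^-2,
    config$prior_effect_sd^-2, config$prior_effect_sd^-2, config$prior_effect_sd^-2)
}

fit_bayes_backend <- function(agg, config) {
  if (!requireNamespace("rjags", quietly = TRUE)) {
    stop("`full_bayes` mode needs the rjags package.", call. = FALSE)
  }
  ids <- sort(unique(agg$participant_id))
  n <- length(ids)
  dat <- list(
    N = nrow(agg), J = n,
    pid = match(agg$participant_id, ids),
    ssc = agg$set_size - 6.5, t = agg$trial_index,
    y = agg$n_correct, m = agg$n_clicks,
    fb = condition_code(agg$feedback, "present"),
    orc = condition_code(agg$task_order, "wm_first")
  )
  inits <- lapply(seq_len(config$chains), function(ch) {
    list(muS = 0, muA = 1, muR = 2,
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = config$seed + ch)
  })
  monitors <- c("muS", "muA", "muR", "slS", "slA", "fbS", "fbA", "fbR",
                "orS", "orA", "orR", "sdS", "sdA", "sdR", "uS", "uA", "uR")
  jm <- rjags::jags.model(textConnection(jags_model_string(config)), data = dat,
                          inits = inits, n.chains = config$chains,
                          n.adapt = config$adapt, quiet = TRUE)
  if (config$warmup > 0) update(jm, config$warmup, progress.bar = "none")
  sm <- rjags::coda.samples(jm, monitors, n.iter = config$iter - config$warmup,
                            progress.bar = "none")

  chains <- lapply(sm, as.matrix)
  draws <- do.call(rbind, chains)
  vars <- colnames(draws)

  diag_tbl <- tibble::tibble(
    term = vars,
    rhat = vapply(vars, function(v) split_rhat(lapply(chains, function(ch) ch[, v])), 0),
    ess = if (requireNamespace("coda", quietly = TRUE)) {
      as.numeric(coda::effectiveSize(sm))[match(vars, colnames(draws))]
    } else NA_real_
  )
  max_rhat <- max(diag_tbl$rhat, na.rm = TRUE)
  if (is.finite(max_rhat) && max_rhat > 1.05) {
    warning(sprintf("sampler not converged: max split-Rhat = %.3f", max_rhat))
  }

  summ <- function(v) {
    x <- draws[, v]
    c(mean(x), stats::sd(x), stats::quantile(x, c(0.025, 0.975)))
  }
  pop_map <- c(muS = "start_mean", muA = "asym_mean", muR = "rate_mean",
               slS = "start_slope", slA = "asym_slope",
               fbS = "feedback_start", fbA = "feedback_asym", fbR = "feedback_rate",
               orS = "order_start", orA = "order_asym", orR = "order_rate",
               sdS = "sd_start", sdA = "sd_asym", sdR = "sd_rate")
  pop <- t(vapply(names(pop_map), summ, numeric(4)))
  population <- tibble::tibble(term = unname(pop_map), estimate = pop[, 1],
                               std_error = pop[, 2], ci_low = pop[, 3], ci_high = pop[, 4])

  # participant-level predictor = population mean + deviation, per draw
  part_rows <- purrr::map_dfr(
    list(c("muS", "uS", "start"), c("muA", "uA", "asym"), c("muR", "uR", "rate")),
    function(tr) {
      u_cols <- paste0(tr[2], "[", seq_len(n), "]")
      lev <- draws[, tr[1]] + draws[, u_cols, drop = FALSE]
      tibble::tibble(
        participant_id = ids, parameter = tr[3],
        estimate = colMeans(lev), sd = apply(lev, 2, stats::sd),
        ci_low = apply(lev, 2, stats::quantile, 0.025),
        ci_high = apply(lev, 2, stats::quantile, 0.975)
      )
    }
  )

  params <- part_rows |>
    dplyr::select("participant_id", "parameter", "estimate") |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "estimate")
  p_hat <- predict_accuracy(
    agg$trial_index, agg$set_size,
    list(sigma0 = params$start[dat$pid], alpha0 = params$asym[dat$pid],
         rho = params$rate[dat$pid],
         sigma_slope = population$estimate[population$term == "start_slope"],
         alpha_slope = population$estimate[population$term == "asym_slope"])
  )
  p_hat <- pmin(pmax(p_hat, 1e-12), 1 - 1e-12)
  loglik <- sum(dat$y * log(p_hat) + (dat$m - dat$y) * log1p(-p_hat))

  list(mode = "full_bayes", population = population, participants = part_rows,
       loglik = loglik,
       diagnostics = list(summary = diag_tbl, max_rhat = max_rhat,
                          min_ess = suppressWarnings(min(diag_tbl$ess, na.rm = TRUE)),
                          chains = config$chains,
                          kept_iterations = config$iter - config$warmup))
}

# split-chain potential scale reduction factor
split_rhat <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(x) {
    h <- length(x) %/% 2L
    list(x[seq_len(h)], x[(h + 1L):(2L * h)])
  }), recursive = FALSE)
  m <- length(halves); nn <- length(halves[[1]])
  if (nn < 2L) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}
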