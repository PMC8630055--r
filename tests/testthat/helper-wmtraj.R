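# shared fixtures, built in code

tiny_cohort <- function(n = 6, seed = 42, ...) {
  simulate_cohort(population_config(n_participants = n, seed = seed, ...))
}

# independently coded per-click log-likelihood: literal product of Bernoulli
# terms, no shared code with curve_loglik
brute_force_loglik <- function(trials, params) {
  total <- 0
  for (i in seq_len(nrow(trials))) {
    row <- trials[i, ]
    pr <- params[params$participant_id == row$participant_id, ]
    sl_s <- if ("sigma_slope" %in% names(pr)) pr$sigma_slope else 0
    sl_a <- if ("alpha_slope" %in% names(pr)) pr$alpha_slope else 0
    S <- 1 / (1 + exp(-(pr$sigma0 + sl_s * (row$set_size - 6.5))))
    A <- 1 / (1 + exp(-(pr$alpha0 + sl_a * (row$set_size - 6.5))))
    tau <- 2^pr$rho + 2
    p <- A + (S - A) * 2^(-(row$trial_index - 1) / tau)
    total <- total + log(if (row$click_correct == 1) p else 1 - p)
  }
  total
}

# independently coded closed-form Bayes factor (gamma/hypergeometric route),
# used as the oracle for the numerical-integration implementation
closed_form_bf_log3 <- function(r, n, kappa = 1 / 3) {
  log_2f1 <- function(a, b, cc, z, maxit = 2e5) {
    logs <- 0; lt <- 0
    for (k in 0:maxit) {
      lt <- lt + log(a + k) + log(b + k) - log(cc + k) - log(k + 1) + log(z)
      logs <- c(logs, lt)
      if (lt < max(logs) - 500) break
    }
    M <- max(logs)
    M + log(sum(exp(logs - M)))
  }
  lbf <- (1 - 2 / kappa) * log(2) + 0.5 * log(pi) - lbeta(1 / kappa, 1 / kappa) +
    lgamma((n + 2 / kappa - 1) / 2) - lgamma((n + 2 / kappa) / 2) +
    log_2f1((n - 1) / 2, (n - 1) / 2, (n + 2 / kappa) / 2, r^2)
  lbf / log(3)
}
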