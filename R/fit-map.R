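# Penalized joint-posterior optimizer (map_fast mode).
#
# Parameter vector: 11 population effects then 3n participant deviations:
#   [muS, muA, muR, slS, slA, fbS, fbA, fbR, orS, orA, orR,
#    uS_1..n, uA_1..n, uR_1..n]
# The likelihood works on per-trial binomial counts; the gradient is
# analytic (the trajectory is smooth in all parameters).

fit_map_backend <- function(agg, config) {
  ids <- sort(unique(agg$participant_id))
  n <- length(ids)
  pid <- match(agg$participant_id, ids)
  ssc <- agg$set_size - 6.5
  tt <- agg$trial_index
  k <- agg$n_correct
  m <- agg$n_clicks
  fb <- condition_code(agg$feedback, "present")
  or <- condition_code(agg$task_order, "wm_first")
  L2 <- log(2)

  sd_pop <- config$prior_pop_sd
  sd_sl <- config$prior_slope_sd
  sd_eff <- config$prior_effect_sd
  sd_dev <- unname(config$prior_dev_sd[c(1, 2, 3)])

  iS <- 12:(11 + n); iA <- (12 + n):(11 + 2 * n); iR <- (12 + 2 * n):(11 + 3 * n)
  clip_hits <- 0L

  parts <- function(th) {
    list(mu = th[1:3], sl = th[4:5], fbE = th[6:8], orE = th[9:11],
         uS = th[iS], uA = th[iA], uR = th[iR])
  }
  forward <- function(p_) {
    etaS <- p_$mu[1] + p_$uS[pid] + p_$sl[1] * ssc + p_$fbE[1] * fb + p_$orE[1] * or
    etaA <- p_$mu[2] + p_$uA[pid] + p_$sl[2] * ssc + p_$fbE[2] * fb + p_$orE[2] * or
    rho  <- p_$mu[3] + p_$uR[pid] + p_$fbE[3] * fb + p_$orE[3] * or
    if (any(abs(etaS) > ETA_CLIP) || any(abs(etaA) > ETA_CLIP)) {
      clip_hits <<- clip_hits + 1L
    }
    S <- stats::plogis(clip_eta(etaS)); A <- stats::plogis(clip_eta(etaA))
    tau <- 2^rho + 2
    w <- 2^(-(tt - 1) / tau)
    p <- pmin(pmax(A + (S - A) * w, 1e-12), 1 - 1e-12)
    list(S = S, A = A, tau = tau, w = w, p = p, rho = rho)
  }
  penalty <- function(p_) {
    sum(p_$mu^2) / (2 * sd_pop^2) + sum(p_$sl^2) / (2 * sd_sl^2) +
      (sum(p_$fbE^2) + sum(p_$orE^2)) / (2 * sd_eff^2) +
      sum(p_$uS^2) / (2 * sd_dev[1]^2) + sum(p_$uA^2) / (2 * sd_dev[2]^2) +
      sum(p_$uR^2) / (2 * sd_dev[3]^2)
  }
  objective <- function(th) {
    p_ <- parts(th); f <- forward(p_)
    -(sum(k * log(f$p) + (m - k) * log1p(-f$p))) + penalty(p_)
  }
  gradient <- function(th) {
    p_ <- parts(th); f <- forward(p_)
    dldp <- k / f$p - (m - k) / (1 - f$p)
    gS <- dldp * f$w * f$S * (1 - f$S)
    gA <- dldp * (1 - f$w) * f$A * (1 - f$A)
    gR <- dldp * (f$S - f$A) * f$w * L2 * (tt - 1) / f$tau^2 * 2^f$rho * L2
    g <- numeric(length(th))
    g[1] <- sum(gS); g[2] <- sum(gA); g[3] <- sum(gR)
    g[4] <- sum(gS * ssc); g[5] <- sum(gA * ssc)
    g[6] <- sum(gS * fb); g[7] <- sum(gA * fb); g[8] <- sum(gR * fb)
    g[9] <- sum(gS * or); g[10] <- sum(gA * or); g[11] <- sum(gR * or)
    g[iS] <- rowsum(gS, pid)[, 1]
    g[iA] <- rowsum(gA, pid)[, 1]
    g[iR] <- rowsum(gR, pid)[, 1]
    -g + c(p_$mu / sd_pop^2, p_$sl / sd_sl^2, p_$fbE / sd_eff^2, p_$orE / sd_eff^2,
           p_$uS / sd_dev[1]^2, p_$uA / sd_dev[2]^2, p_$uR / sd_dev[3]^2)
  }

  th0 <- c(0, 1, 2, -0.3, -0.3, rep(0, 6), rep(0, 3 * n))
  opt <- withr::with_seed(config$seed,
    stats::optim(th0, objective, gradient, method = "L-BFGS-B",
                 control = list(maxit = config$max_iter, factr = 1e7))
  )
  if (opt$convergence != 0) {
    warning(sprintf("optimizer did not report clean convergence (code %d): %s",
                    opt$convergence, opt$message))
  }
  p_ <- parts(opt$par)
  f <- forward(p_)
  loglik <- sum(k * log(f$p) + (m - k) * log1p(-f$p))

  pop_terms <- c("start_mean", "asym_mean", "rate_mean", "start_slope", "asym_slope",
                 "feedback_start", "feedback_asym", "feedback_rate",
                 "order_start", "order_asym", "order_rate")
  se <- rep(NA_real_, 11)
  if (config$se) {
    H <- stats::optimHess(opt$par, objective, gradient)
    cov_pop <- tryCatch(solve(H)[1:11, 1:11], error = function(e) NULL)
    if (!is.null(cov_pop)) {
      vars <- diag(cov_pop)
      se <- ifelse(vars > 0, sqrt(vars), NA_real_)
    }
  }
  population <- tibble::tibble(
    term = pop_terms, estimate = opt$par[1:11], std_error = se,
    ci_low = opt$par[1:11] - stats::qnorm(0.975) * se,
    ci_high = opt$par[1:11] + stats::qnorm(0.975) * se
  )
  participants <- tibble::tibble(
    participant_id = rep(ids, 3L),
    parameter = rep(c("start", "asym", "rate"), each = n),
    estimate = c(p_$mu[1] + p_$uS, p_$mu[2] + p_$uA, p_$mu[3] + p_$uR),
    sd = NA_real_, ci_low = NA_real_, ci_high = NA_real_
  )
  list(mode = "map_fast", population = population, participants = participants,
       loglik = loglik,
       diagnostics = list(convergence = opt$convergence,
                          counts = opt$counts, logpost = -opt$value,
                          grad_norm = sqrt(sum(gradient(opt$par)^2)),
                          clip_events = clip_hits))
}
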