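---
title: "Modeling working-memory performance trajectories and their links to fluid intelligence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling working-memory performance trajectories and their links to fluid intelligence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmtraj)
library(dplyr)
```

## The problem

Individual-differences research routinely aggregates task performance over
trials — a percent correct, a d-prime — and correlates the aggregate with
another construct. That aggregation assumes performance is stationary over
the task. On a spatial span (Corsi-style) working-memory task it is not:
accuracy changes within a single session of 68 trials. When performance
changes, an overall score confounds at least three distinct quantities —
where a participant starts, how fast they change, and where they end up —
and any correlation with, say, fluid intelligence (Gf) is ambiguous about
which of these carries the relationship.

`wmtraj` implements a time-sensitive alternative: a nonlinear mixed-effects
model of trial-by-trial accuracy that separates each participant's
trajectory into an initial accuracy, a rate of change, and an asymptotic
("final") accuracy, followed by an association layer that relates each
component to Gf with bootstrap intervals, default-prior Bayes factors, and
joint regression.

## The trajectory model

Every mouse click is one Bernoulli observation. For a click in trial $t$
with set size $s$, the success probability is an exponential approach from
a start accuracy $S$ to an asymptote $A$:

$$p(t) = A + (S - A)\, 2^{-(t-1)/\tau},$$

with

$$S = \mathrm{logit}^{-1}\!\big(\sigma_0 + \sigma_s (s - 6.5)\big), \qquad
  A = \mathrm{logit}^{-1}\!\big(\alpha_0 + \alpha_s (s - 6.5)\big), \qquad
  \tau = 2^{\rho} + 2 .$$

Design of the parameterization:

* **Logit links for start and asymptote.** Unbounded predictors map to
  accuracies in $(0,1)$, and set size enters linearly on the logit scale —
  a participant-level psychometric function. Set size is centered at 6.5,
  the mean of the main set sizes $\{5,6,7,8\}$, so $\sigma_0$ and
  $\alpha_0$ are the participant's predictors at intermediate difficulty.
* **Binary-log rate with a +2 offset.** $\tau$ is the number of trials
  needed to close half the start–asymptote gap: the base-2 decay makes
  $p(1+\tau) = (S+A)/2$ exactly. The additive offset bounds $\tau$ above 2
  trials, keeping the sampler away from degenerate instant-learning
  solutions.
* **Random effects** on $\sigma_0$, $\alpha_0$, $\rho$ only (one deviation
  per participant per component); set-size slopes and the condition fixed
  effects (feedback presence, task order) are population-level, entered on
  all three parameter predictors with $\pm 0.5$ effect coding. This is the
  smallest structure that gives every participant their own three-component
  trajectory while keeping the psychometric slopes shared.
* **Numerical guard.** Linear predictors are clipped at $\pm 35$ inside the
  fitting likelihood so probabilities never reach exactly 0 or 1; clip
  events are counted in the fit diagnostics. The standalone likelihood
  (`curve_loglik()`) deliberately does *not* clip, and raises an error if a
  saturated probability contradicts an observed click.

Catch trials (set size 3) are included in the likelihood with the same
centered covariate, matching the fully disaggregated treatment of the
click-level data; `fit_config(include_catch = FALSE)` removes them for
sensitivity analysis.

## Estimation modes

`fit_trajectories()` has two modes sharing one prior structure
(normal(0, 5) on population means, normal(0, 2) on slopes and condition
effects):

* **`map_fast`** maximizes the penalized joint posterior with analytic
  gradients (L-BFGS-B), treating the participant-deviation scales as fixed
  weakly-informative constants (SD 1 for start and asymptote, 1.25 for
  rate). Joint optimization of deviations *and* their hierarchical SDs
  degenerates (the joint mode collapses toward zero variance), so this mode
  does not estimate the SDs; point estimates and ranks are what it is for.
  A 87-participant cohort fits in about a second.
* **`full_bayes`** samples the full hierarchy with JAGS, placing
  half-normal(0, 1) priors on the deviation SDs. The reference budget is 4
  chains × 5000 iterations with 3000 discarded as warm-up; the budget is
  configurable, split-chain $\widehat R$ and effective sample sizes are
  reported for every monitored quantity, and $\widehat R > 1.05$ triggers a
  warning rather than silence. Clicks are pooled to per-trial binomial
  counts before sampling — an identical likelihood at a fraction of the
  graph size.

The suite checks that the two modes agree in rank (Spearman $\ge 0.9$) on
all three extracted components for a 30-participant cohort under a short
sampling budget.

Point estimates are extracted as the participant-level posterior means
(`full_bayes`) or joint-mode values (`map_fast`) of
$\sigma_0 + u_{\sigma,i}$ etc., then transformed: `initial_accuracy` and
`final_accuracy` are inverse-logits at the centered set size, the rate stays
on the $\rho$ scale (a time constant — larger is slower), and
`overall_accuracy` is the raw click-level mean, the aggregate a conventional
analysis would use.

## The synthetic cohort generator

The study's raw data are not bundled; `simulate_cohort()` generates cohorts
with the statistical structure the analysis assumes, so every downstream
stage is testable offline. The generator and the likelihood share one
data-generating story: clicks within a trial are conditionally independent
given the trial's predicted accuracy (the Bernoulli disaggregation implies
no within-sequence position structure, and the generator deliberately adds
none).

Defaults (all configurable through `population_config()`):

| quantity | default | rationale |
|---|---|---|
| cohort size | 87 | the study's retained sample |
| start logit $\sigma_0$ | $-0.5 \pm 0.75$ | ≈ 38% initial accuracy at set size 6.5 — well above floor, far below asymptote |
| asymptote logit $\alpha_0$ | $1.4 \pm 0.8$ | ≈ 80% final accuracy, plausible for spans of 5–8 |
| rate $\rho$ | $2.6 \pm 1.2$ | $\tau \approx 8$ trials median; large spread creates real individual differences in learning speed |
| set-size slopes | $-0.35$ / $-0.5$ | accuracy declines with span length; catch trials at set size 3 come out near ceiling |
| condition effects | 0 | the study found none reliable; the machinery stays exercised and configurable |
| Gf loadings | $+0.33$ (asymptote), $-0.30$ (rate), none (start) | the two dissociable links, at the published correlation sizes |

Gf is generated on the latent link scales —
$\mathrm{gf} = 0.33\,z(\alpha_0) - 0.30\,z(\rho) + \varepsilon$ — with the
noise SD completed to unit variance, so the *population* correlations equal
the loadings exactly, and the start component has zero partial association
with Gf by construction. Half the cohort is labeled feedback-present and
task order alternates, mirroring counterbalancing.

What the generator does **not** emulate: within-sequence position effects,
response-time structure, trial-to-trial dependencies beyond the smooth
trajectory, dropout, or item-level Gf responses (Gf enters as one score per
participant, as the composite-of-z-scores definition implies). A passing
recovery test therefore shows the estimation machinery works under the
model's own assumptions — not that real span data satisfy them.

## What the simulations show — and their honest limits

Parameter recovery at study scale (87 participants, `map_fast`) is strong
for the asymptote (r ≈ 0.95 between true and recovered), good for the start
(≈ 0.85), and moderate for the rate (≈ 0.6–0.75 depending on the draw).
The rate ceiling is informational, not algorithmic: even with a
participant's true start and asymptote given, only the handful of
transition trials carries rate information, so rate recovery stays well
below the asymptote's however the estimator is tuned.

That ceiling matters for the end-to-end dissociation. With a true latent
correlation of 0.33 at $n = 87$, the sample correlation has an SE near 0.1,
and a default-prior Bayes factor exceeds 3 only for $|r| \gtrsim 0.25$; the
rate link is additionally attenuated by recovery reliability. A single
simulated cohort therefore reproduces the qualitative pattern — evidence
for the final and rate links, absence of evidence for the start link, and a
near-isomorphism between overall and final accuracy — only part of the
time, exactly as one expects of a single study at this sample size. The
acceptance suite runs ten replicate cohorts and records how often the full
conjunction holds; slower-learning configurations raise rate recovery but
push the overall–final correlation down (more trials spent in transition),
so no plausible configuration makes the conjunction routine. We regard this
as a faithful property of the design, and kept the generator at the
configuration above rather than distorting it to force a pattern.

## The association layer

* **Gf composite**: per-task z-scores over the cohort, averaged.
* **Correlations** with percentile bootstrap CIs (10,000 paired resamples
  by default, seeded).
* **Bayes factors** for each correlation, via numerical integration of the
  reduced likelihood of $r$ against a stretched-beta prior on $\rho$ of
  width 1/3 (the conventional "medium" default), reported as $\log_3$ BF so
  that $\pm 1$ marks 3:1 evidence either way. The implementation is checked
  against an independently coded closed-form (gamma/hypergeometric)
  expression. At the published sample statistics $(r = .33, n = 87)$ and
  $(r = -.30, n = 87)$ it reproduces the published $\log_3$ BFs within 0.1.
  A caveat worth knowing: at $|r| = .96$ the $\log_3$ BF moves by ≈ 4.8
  units per 0.001 of $r$, so two-decimal rounding of a reported correlation
  leaves more than $\pm 2$ units of uncertainty in any recomputation.
* **Joint regression** of Gf on rate and final accuracy with t-based CIs
  and semi-partial $\Delta R^2$ (the $R^2$ drop when the predictor is
  removed), plus a Huber M-estimation refit as the leverage check.
* **Power analytics** by the Fisher-z approximation, with both rejection
  tails retained so that power at $r = 0$ equals $\alpha$ exactly.

## Screening

Chance-level performance on the matrix-reasoning tasks is screened with an
exact one-tailed binomial test against the 12.5% guessing rate: the
threshold is the largest score whose upper-tail probability still reaches
$\alpha$, so a true guesser survives with probability at most $\alpha$.
Item counts are instrument properties and therefore configuration inputs.
Catch-trial accuracy strictly below 50% excludes; exactly 50% retains (the
boundary is untestable against the published analysis, which excluded
nobody by this rule, so the lenient reading is documented and used).

## Reproducibility and problem sizes

Every stochastic function takes a seed; `run_pipeline()` threads one seed
through simulation, fitting, and bootstrapping and writes a manifest
(config echo, seed, package version) beside its artifacts. The test suite
sizes its simulations to run in about two minutes total: recovery checks
use cohorts of 30–87 participants, the sampler comparison uses a
30-participant cohort under a reduced budget, bootstrap coverage uses 400
replications at $n = 87$, and the dissociation property uses ten replicate
cohorts.

## A worked run

```{r example, eval = FALSE}
cohort <- simulate_cohort(population_config(seed = 1))
fit <- fit_trajectories(cohort$trials, fit_config(mode = "map_fast", seed = 1))
est <- extract_estimates(fit)
assoc <- associate_components(est, cohort$participants[, c("participant_id", "gf")],
                              n_boot = 5000, seed = 1)
assoc
autoplot(assoc)
```

## Known limitations

* Only the exponential-change family is implemented; competing growth-curve
  families (linear, log-linear) are out of scope by design, as the point of
  the fully nonlinear form is to avoid conflating trajectory components.
* `map_fast` reports no participant-level posterior spread; use
  `full_bayes` when interval statements about individual participants
  matter.
* The rate component's recovery reliability is bounded by the task design
  (68 trials, most of them post-transition); analyses weighting the rate
  component should expect attenuation of its correlations.
* Whether the original analysis included catch trials in the fit is not
  documented; the default here includes them, with a switch to exclude.
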