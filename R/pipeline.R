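#' Configuration for the end-to-end pipeline
#'
#' @param out_dir Output directory (created if needed). Every run writes a
#'   `manifest.yaml` echoing the configuration, the seed and the package
#'   version alongside its artifacts.
#' @param seed Global seed; every stage's randomness derives from it.
#' @param stages Stages to run, in pipeline order, among `"simulate"`,
#'   `"screen"`, `"fit"`, `"extract"`, `"associate"`.
#' @param population A [population_config()] for the simulate stage; its
#'   seed is overridden by `seed`.
#' @param fit_mode `"map_fast"` or `"full_bayes"`.
#' @param n_boot Bootstrap resamples for the associate stage.
#' @param trials_path Input CSV of click-level trials (required when the
#'   simulate stage is skipped).
#' @param gf_path Input CSV with `participant_id, gf` (required for the
#'   associate stage when simulate is skipped).
#' @param verbose Print stage progress.
#' @return A list of class `wm_run_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("simulate", "screen", "fit", "extract", "associate"),
                            population = population_config(),
                            fit_mode = "map_fast", n_boot = 2000L,
                            trials_path = NULL, gf_path = NULL, verbose = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
         population = population, fit_mode = fit_mode, n_boot = as.integer(n_boot),
         trials_path = trials_path, gf_path = gf_path, verbose = isTRUE(verbose)),
    class = "wm_run_config"
  )
}

#' Run the analysis pipeline
#'
#' Executes simulate -> screen -> fit -> extract -> associate (any prefix
#' or subset in that order) and writes artifacts and a manifest to
#' `config$out_dir`. Inputs are validated and all stage computation
#' completes before any file is written, so a failing run leaves no
#' partial outputs. All randomness flows from `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`cohort` or
#'   `trials`, `screen`, `fit`, `estimates`, `associations`, `regression`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "wm_run_config"))
  say <- function(...) if (config$verbose) message(sprintf(...))
  stages <- config$stages
  res <- list()

  if ("simulate" %in% stages) {
    pop <- config$population
    pop$seed <- config$seed
    say("simulate: %d participants (seed %d)", pop$n_participants, pop$seed)
    cohort <- simulate_cohort(pop)
    res$cohort <- cohort
    trials <- cohort$trials
    gf <- cohort$participants[, c("participant_id", "gf")]
  } else {
    if (is.null(config$trials_path)) {
      stop("`trials_path` is required when the simulate stage is skipped.", call. = FALSE)
    }
    say("load: %s", config$trials_path)
    trials <- read_trials(config$trials_path)
    gf <- NULL
    if (!is.null(config$gf_path)) {
      if (!file.exists(config$gf_path)) {
        stop(sprintf("file not found: %s", config$gf_path), call. = FALSE)
      }
      gf <- readr::read_csv(config$gf_path, show_col_types = FALSE, progress = FALSE)
    }
  }
  res$trials <- trials

  if ("screen" %in% stages) {
    say("screen: catch-trial criterion")
    res$screen <- screen_cohort(catch = catch_accuracy(trials))
    drop <- excluded_participants(res$screen)
    if (length(drop)) {
      say("screen: excluding %d participant(s)", length(drop))
      trials <- dplyr::filter(trials, !.data$participant_id %in% drop)
    }
  }

  if ("fit" %in% stages) {
    say("fit: %s", config$fit_mode)
    res$fit <- fit_trajectories(trials, fit_config(mode = config$fit_mode,
                                                   seed = config$seed))
  }
  if ("extract" %in% stages) {
    if (is.null(res$fit)) stop("extract stage needs the fit stage.", call. = FALSE)
    res$estimates <- extract_estimates(res$fit)
  }
  if ("associate" %in% stages) {
    if (is.null(res$estimates)) stop("associate stage needs the extract stage.", call. = FALSE)
    if (is.null(gf)) stop("associate stage needs Gf scores (`gf_path`).", call. = FALSE)
    say("associate: %d bootstrap resamples", config$n_boot)
    res$associations <- associate_components(res$estimates, gf,
                                             n_boot = config$n_boot, seed = config$seed)
    reg_dat <- dplyr::inner_join(res$estimates, gf, by = "participant_id")
    res$regression <- joint_regression(reg_dat)
  }

  manifest <- list(
    package = "wmtraj",
    version = as.character(utils::packageVersion("wmtraj")),
    seed = config$seed,
    stages = stages,
    fit_mode = config$fit_mode,
    n_boot = config$n_boot,
    population = if ("simulate" %in% stages) {
      unclass(config$population)[c("n_participants", "start_mean", "start_sd",
                                   "asym_mean", "asym_sd", "rate_mean", "rate_sd",
                                   "start_slope", "asym_slope", "gf_loading_asym",
                                   "gf_loading_rate", "gf_noise_sd")]
    },
    inputs = list(trials_path = config$trials_path, gf_path = config$gf_path)
  )
  res$manifest <- manifest

  # all computation done; now write artifacts
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  yaml::write_yaml(manifest, out("manifest.yaml"))
  readr::write_csv(build_schedule(), out("schedule.csv"))
  write_trials(res$trials, out("trials.csv"))
  if (!is.null(res$cohort)) {
    readr::write_csv(res$cohort$participants, out("participants.csv"))
  }
  if (!is.null(res$screen)) readr::write_csv(res$screen, out("screen.csv"))
  if (!is.null(res$estimates)) write_estimates(res$estimates, out("estimates.csv"))
  if (!is.null(res$associations)) readr::write_csv(res$associations, out("associations.csv"))
  if (!is.null(res$regression)) readr::write_csv(res$regression$coefficients, out("regression.csv"))
  write_report(list(fit = res$fit, exclusions = res$screen,
                    associations = res$associations, regression = res$regression),
               out("report.txt"))
  say("wrote artifacts to %s", config$out_dir)
  invisible(res)
}
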