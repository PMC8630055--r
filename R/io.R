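#' Read a click-level trial table
#'
#' Reads the comma-separated interchange format (header row, UTF-8, "."
#' decimal) and validates the schema: required columns, binary
#' correctness, known set sizes and in-range trial indices. Violations are
#' reported with their row numbers. Unknown extra columns are kept with a
#' warning. An empty file (no data rows) is an explicit error, not an
#' empty success. A `mapping` renames deposit-specific column names onto
#' the package schema before validation, so externally archived data can be
#' adapted without a bespoke parser.
#'
#' @param path CSV file path.
#' @param mapping Optional named character vector, `c(ours = "theirs")`,
#'   applied before validation.
#' @return Validated click-level tibble.
#' @export
read_trials <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  trials <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(trials) == 0L) {
    stop(sprintf("empty input: %s contains no data rows.", path), call. = FALSE)
  }
  if (!is.null(mapping)) {
    for (ours in names(mapping)) {
      theirs <- mapping[[ours]]
      if (!theirs %in% names(trials)) {
        stop(sprintf("mapped column `%s` not present in %s", theirs, path), call. = FALSE)
      }
      names(trials)[names(trials) == theirs] <- ours
    }
  }
  required <- c("participant_id", "trial_index", "set_size", "click_correct")
  missing <- setdiff(required, names(trials))
  if (length(missing)) {
    stop(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  known <- c(required, "click_index", "feedback", "task_order")
  extra <- setdiff(names(trials), known)
  if (length(extra)) {
    warning(sprintf("preserving unknown column(s): %s", paste(extra, collapse = ", ")))
  }
  bad_rows <- function(ok) which(!ok)
  checks <- list(
    "click_correct must be 0 or 1" = trials$click_correct %in% c(0, 1),
    "set_size must be one of 3, 5, 6, 7, 8" = trials$set_size %in% c(3, 5, 6, 7, 8),
    "trial_index must lie in 1..68" =
      trials$trial_index >= 1 & trials$trial_index <= 68
  )
  for (msg in names(checks)) {
    bad <- bad_rows(checks[[msg]])
    if (length(bad)) {
      stop(sprintf("%s (row%s %s)", msg, if (length(bad) > 1) "s" else "",
                   paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
    }
  }
  trials
}

#' Write a click-level trial table
#' @param trials Click-level tibble.
#' @param path Destination CSV path.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' Write participant estimates
#' @param estimates Tibble from [extract_estimates()].
#' @param path Destination CSV path.
#' @export
write_estimates <- function(estimates, path) {
  readr::write_csv(estimates, path)
  invisible(path)
}

#' Write a plain-text analysis report
#'
#' @param results Named list; recognized elements are `associations`
#'   (from [associate_components()]), `regression` (a [joint_regression()]
#'   object), `power` (named numbers), `fit` (a `wm_fit`), and
#'   `exclusions` (from [screen_cohort()]). Anything else is printed with
#'   its name.
#' @param path Destination text file.
#' @export
write_report <- function(results, path) {
  lines <- c("working-memory trajectory analysis report",
             strrep("=", 42), "")
  fmt_tbl <- function(df) utils::capture.output(print(as.data.frame(df), row.names = FALSE))
  if (!is.null(results$fit)) {
    f <- results$fit
    lines <- c(lines, sprintf("model fit: mode=%s participants=%d loglik=%.2f",
                              f$mode, f$n_participants, f$loglik))
    if (f$mode == "full_bayes") {
      lines <- c(lines, sprintf("  max split-Rhat=%.3f min ESS=%.0f",
                                f$diagnostics$max_rhat, f$diagnostics$min_ess))
    }
    lines <- c(lines, fmt_tbl(f$population), "")
  }
  if (!is.null(results$exclusions)) {
    lines <- c(lines, "exclusion screen:", fmt_tbl(results$exclusions), "")
  }
  if (!is.null(results$associations)) {
    lines <- c(lines, "associations:", fmt_tbl(results$associations), "")
  }
  if (!is.null(results$regression)) {
    r <- results$regression
    lines <- c(lines, sprintf("joint regression (n=%d, R^2=%.3f):", r$n, r$r_squared),
               fmt_tbl(r$coefficients), "")
  }
  if (!is.null(results$power)) {
    lines <- c(lines, "power:",
               paste(sprintf("  %s = %.4f", names(results$power), results$power)), "")
  }
  writeLines(lines, path)
  invisible(path)
}
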