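# Estimation of the metric parameters from a recorded speller session.
# Each row of a performance log is one recorded trial: the user's intention
# (selection or skip), the system's action, correctness when a selection was
# both intended and made, the number of stimulus sequences presented, the
# sequence duration, and the on-screen keyboard size.

log_columns <- c("intention", "system_action", "correct", "n_sequences",
                 "sequence_duration_ms", "keyboard_size", "is_correction")

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("bci_format_error", "error")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("bci_validation_error",
                                             "error")))
}

validate_log <- function(records) {
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      stop_validation(what, " (data row",
                      if (length(rows) > 1L) "s", " ",
                      paste(utils::head(rows, 5L), collapse = ", "),
                      if (length(rows) > 5L) ", ...", ")")
  }
  bad(!records$intention %in% c("selection", "skip"),
      "'intention' must be 'selection' or 'skip'")
  bad(!records$system_action %in% c("selection", "skip"),
      "'system_action' must be 'selection' or 'skip'")
  made_when_intended <- records$intention == "selection" &
    records$system_action == "selection"
  bad(made_when_intended & is.na(records$correct),
      "'correct' must be set when a selection is intended and made")
  bad(!made_when_intended & !is.na(records$correct),
      "'correct' is defined only when a selection is intended and made")
  bad(is.na(records$n_sequences) | records$n_sequences < 1 |
        records$n_sequences != round(records$n_sequences),
      "'n_sequences' must be a positive integer")
  bad(is.na(records$sequence_duration_ms) |
        records$sequence_duration_ms <= 0,
      "'sequence_duration_ms' must be positive")
  bad(is.na(records$keyboard_size) | records$keyboard_size < 2,
      "'keyboard_size' must be at least 2")
  bad(is.na(records$is_correction), "'is_correction' must be TRUE or FALSE")
  invisible(records)
}

#' Read or write a speller performance log
#'
#' A performance log is comma-separated text with a header row and columns
#' `intention`, `system_action`, `correct`, `n_sequences`,
#' `sequence_duration_ms`, `keyboard_size`, `is_correction`; one row per
#' recorded trial.  `correct` is empty (NA) except where a selection was
#' both intended and made.  Malformed files raise a format error; rows
#' violating the schema raise a validation error naming the offending rows.
#'
#' @param path Path to the CSV file.
#' @return `read_performance_log()`: a validated data frame of trial
#'   records.  `write_performance_log()` returns `path` invisibly.
#' @export
#' @examples
#' log <- read_performance_log(
#'   system.file("extdata", "session_synthetic.csv", package = "bciutility"))
#' nrow(log)
read_performance_log <- function(path) {
  if (!file.exists(path)) stop_format("performance log not found: ", path)
  records <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop_format("cannot parse '", path, "': ",
                                    conditionMessage(e)))
  if (nrow(records) == 0L)
    stop_format("performance log '", path, "' contains no trials")
  missing <- setdiff(log_columns, names(records))
  if (length(missing))
    stop_format("performance log '", path, "' is missing column(s): ",
                paste(missing, collapse = ", "))
  records <- records[log_columns]
  records$correct <- as.logical(records$correct)
  records$is_correction <- as.logical(records$is_correction)
  validate_log(records)
  records
}

#' @param records A data frame of trial records.
#' @rdname read_performance_log
#' @export
write_performance_log <- function(records, path) {
  validate_log(records[log_columns])
  utils::write.csv(records[log_columns], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Estimate the scenario probabilities from a session
#'
#' All probabilities are exact ratios of the underlying counts:
#' selections-made / intended-selections (`p_sel_given_sel`),
#' correct / made-when-intended (`p_correct`),
#' correct-skips / intended-skips (`p_skip_given_skip`), and
#' intended-selections / total trials (`pi_sel_i`).  A zero denominator
#' yields `NA` for that parameter rather than an error.
#'
#' @param records A performance log (see [read_performance_log()]).
#' @param exclude_corrections If `TRUE`, `pi_sel_i` is computed over
#'   non-correction trials only (the initially-intended outcomes); the
#'   accuracy estimates always use all trials.
#' @return A list with the four probability estimates and a `counts` list
#'   of the integer numerators and denominators.
#' @export
estimate_probabilities <- function(records, exclude_corrections = FALSE) {
  validate_log(records[log_columns])
  int_sel <- records$intention == "selection"
  made <- records$system_action == "selection"
  counts <- list(
    intended_selections = sum(int_sel),
    selections_made = sum(int_sel & made),
    correct_selections = sum(int_sel & made & records$correct %in% TRUE),
    intended_skips = sum(!int_sel),
    correct_skips = sum(!int_sel & !made),
    n_trials = nrow(records)
  )
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  pi_base <- if (exclude_corrections) !records$is_correction
             else rep(TRUE, nrow(records))
  list(
    p_sel_given_sel = ratio(counts$selections_made,
                            counts$intended_selections),
    p_correct = ratio(counts$correct_selections, counts$selections_made),
    p_skip_given_skip = ratio(counts$correct_skips, counts$intended_skips),
    pi_sel_i = ratio(sum(int_sel & pi_base), sum(pi_base)),
    counts = counts
  )
}

#' Estimate trial durations from a session
#'
#' The complete-trial duration is estimated by averaging the would-be
#' complete duration of every trial (`sequences_per_complete_trial` times
#' the trial's sequence duration) and adding the inter-selection delay; the
#' expected decided-trial duration by averaging the realized duration
#' (`n_sequences` times the sequence duration) of the selection-producing
#' trials and adding the same delay.
#'
#' @inheritParams estimate_probabilities
#' @param inter_selection_delay_ms Pause between selections, milliseconds
#'   (a known constant of the protocol, not inferred).
#' @param sequences_per_complete_trial Number of sequences in a complete
#'   (maximum-length) trial.
#' @return A list with `c_hat` and `c_T_hat` in seconds (`c_hat` is `NA`
#'   when no trial produced a selection) and the same values in
#'   milliseconds (`c_hat_ms`, `c_T_hat_ms`).
#' @export
estimate_durations <- function(records, inter_selection_delay_ms,
                               sequences_per_complete_trial) {
  validate_log(records[log_columns])
  chk_nonneg(inter_selection_delay_ms, "inter_selection_delay_ms")
  chk_count(sequences_per_complete_trial, "sequences_per_complete_trial")
  c_T_ms <- mean(sequences_per_complete_trial *
                   records$sequence_duration_ms) + inter_selection_delay_ms
  made <- records$system_action == "selection"
  c_ms <- if (any(made)) {
    mean(records$n_sequences[made] * records$sequence_duration_ms[made]) +
      inter_selection_delay_ms
  } else NA_real_
  list(c_hat = c_ms / 1000, c_T_hat = c_T_ms / 1000,
       c_hat_ms = c_ms, c_T_hat_ms = c_T_ms)
}

#' BCI-Utility of a recorded session
#'
#' Composes the probability estimators, the duration estimators, and the
#' benefit (mean `log2(keyboard_size)` over trials unless benefits are
#' supplied), then evaluates the general-scenario expected times and the
#' BCI-Utility for the session.
#'
#' @inheritParams estimate_durations
#' @param b_sel,b_skip Benefits in bits; default to the mean
#'   `log2(keyboard_size)` across all trials.
#' @param exclude_corrections Passed to [estimate_probabilities()].
#' @return An object of class `bci_session`: counts, estimated parameters
#'   (exact count ratios), estimated durations, benefits, expected times,
#'   and the `utility` (a `bci_utility`; `NA` value when a needed parameter
#'   is undefined, with the undefined parameters named in `undefined`).
#' @export
#' @examples
#' log <- read_performance_log(
#'   system.file("extdata", "session_synthetic.csv", package = "bciutility"))
#' session_utility(log, inter_selection_delay_ms = 10000,
#'                 sequences_per_complete_trial = 3,
#'                 b_sel = 5.8, b_skip = 5.8)
session_utility <- function(records, inter_selection_delay_ms,
                            sequences_per_complete_trial,
                            b_sel = NULL, b_skip = NULL,
                            exclude_corrections = FALSE) {
  probs <- estimate_probabilities(records, exclude_corrections)
  durs <- estimate_durations(records, inter_selection_delay_ms,
                             sequences_per_complete_trial)
  b_hat <- average_benefit(records$keyboard_size)
  if (is.null(b_sel)) b_sel <- b_hat
  if (is.null(b_skip)) b_skip <- b_hat

  par_vals <- list(pi_sel_i = probs$pi_sel_i,
                   p_sel_given_sel = probs$p_sel_given_sel,
                   p_correct = probs$p_correct,
                   p_skip_given_skip = probs$p_skip_given_skip,
                   c_hat = durs$c_hat)
  undefined <- names(par_vals)[vapply(par_vals, is.na, logical(1))]

  if (length(undefined) == 0L) {
    pars <- full_params(probs$pi_sel_i, probs$p_sel_given_sel,
                        probs$p_correct, 1 - probs$p_skip_given_skip,
                        c = durs$c_hat, c_T = durs$c_T_hat,
                        b_sel = b_sel, b_skip = b_skip)
    times <- expected_times(pars)
    utility <- utility_full(pars)
  } else {
    pars <- NULL
    times <- structure(list(t_sel = NA_real_, t_bs = NA_real_,
                            t_skip = NA_real_), class = "bci_times")
    utility <- structure(list(value = NA_real_, regime = "valid"),
                         class = "bci_utility")
  }

  structure(list(
    counts = probs$counts,
    p_sel_given_sel = probs$p_sel_given_sel,
    p_correct = probs$p_correct,
    p_skip_given_skip = probs$p_skip_given_skip,
    pi_sel_i = probs$pi_sel_i,
    c_hat = durs$c_hat, c_T_hat = durs$c_T_hat,
    b_hat = b_hat, b_sel = b_sel, b_skip = b_skip,
    params = pars, times = times, utility = utility,
    undefined = undefined,
    exclude_corrections = exclude_corrections
  ), class = "bci_session")
}

#' @export
print.bci_session <- function(x, ...) {
  cat("BCI speller session summary\n")
  cat(sprintf("  trials: %d (%d intended selections, %d intended skips)\n",
              x$counts$n_trials, x$counts$intended_selections,
              x$counts$intended_skips))
  pct <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%",
                                                            100 * v)
  cat(sprintf("  p_sel_given_sel   %s  (%d/%d)\n", pct(x$p_sel_given_sel),
              x$counts$selections_made, x$counts$intended_selections))
  cat(sprintf("  p_correct         %s  (%d/%d)\n", pct(x$p_correct),
              x$counts$correct_selections, x$counts$selections_made))
  cat(sprintf("  p_skip_given_skip %s  (%d/%d)\n", pct(x$p_skip_given_skip),
              x$counts$correct_skips, x$counts$intended_skips))
  cat(sprintf("  pi_sel_i          %s\n", pct(x$pi_sel_i)))
  cat(sprintf("  c = %.2f s, c_T = %.2f s, benefits %.3g / %.3g bits\n",
              x$c_hat, x$c_T_hat, x$b_sel, x$b_skip))
  if (length(x$undefined)) {
    cat("  utility undefined; missing parameter(s): ",
        paste(x$undefined, collapse = ", "), "\n", sep = "")
  } else {
    cat(sprintf("  Tsel = Tbs = %.2f s, Tskip = %.2f s\n",
                x$times$t_sel, x$times$t_skip))
    cat(sprintf("  BCI-Utility: %.3f bit/s\n", x$utility$value))
  }
  invisible(x)
}
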