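#' @keywords internal
stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("bci_param_error", "error")))
}

chk_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_param("'", name, "' must be a single probability in [0, 1]")
  as.numeric(x)
}

chk_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_param("'", name, "' must be a single positive number")
  as.numeric(x)
}

chk_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop_param("'", name, "' must be a single non-negative number")
  as.numeric(x)
}

chk_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    stop_param("'", name, "' must be a single integer >= ", min)
  as.integer(x)
}

chk_c_cT <- function(c, c_T) {
  if (c > c_T)
    stop_param("'c' must not exceed 'c_T' (expected decided-trial time ",
               "cannot be longer than a complete trial)")
}

new_params <- function(fields, class) {
  structure(fields, class = c(class, "bci_params"))
}

#' Parameters of a fully synchronous (plain) speller
#'
#' A plain speller always completes every trial (duration `c_T`) and always
#' produces a selection; a wrong selection must be deleted with a backspace.
#'
#' @param p Selection accuracy, the probability that a trial produces the
#'   intended character (or backspace).
#' @param n_outcomes Number of possible outcomes `N` per trial, counting the
#'   backspace key (`N - 1` characters plus backspace).  Must be at least 2.
#' @param c_T Duration of a complete trial, in seconds.
#' @return An object of class `bci_plain_params`.
#' @seealso [utility_plain()]
#' @export
#' @examples
#' plain_params(p = 0.9, n_outcomes = 37, c_T = 31.625)
plain_params <- function(p, n_outcomes, c_T) {
  new_params(list(
    p = chk_prob(p, "p"),
    n_outcomes = chk_count(n_outcomes, "n_outcomes", min = 2L),
    c_T = chk_pos(c_T, "c_T")
  ), "bci_plain_params")
}

#' Parameters of a speller with dynamic stopping
#'
#' Dynamic stopping ends a trial as soon as the accumulated evidence suffices
#' for a decision, so the expected decided-trial duration `c` is at most the
#' complete-trial duration `c_T`.
#'
#' @inheritParams plain_params
#' @param c Expected duration of a trial, in seconds; `0 < c <= c_T`.
#' @return An object of class `bci_dynamic_params`.
#' @seealso [utility_dynamic()]
#' @export
dynamic_params <- function(p, n_outcomes, c, c_T) {
  c <- chk_pos(c, "c"); c_T <- chk_pos(c_T, "c_T"); chk_c_cT(c, c_T)
  new_params(list(
    p = chk_prob(p, "p"),
    n_outcomes = chk_count(n_outcomes, "n_outcomes", min = 2L),
    c = c, c_T = c_T
  ), "bci_dynamic_params")
}

#' Parameters of a speller with abstention and dynamic stopping
#'
#' The speller may abstain: if all sequences complete without sufficient
#' evidence, no selection is produced and the trial is skipped (taking the
#' full `c_T`).  Here every abstention is unintended; the user always wants a
#' selection.
#'
#' @param p_sel Probability that a trial produces a selection (as opposed to
#'   an abstention).
#' @param p_correct Probability that a selection is correct, given that a
#'   selection was made.
#' @inheritParams dynamic_params
#' @return An object of class `bci_abstention_params`.
#' @seealso [utility_abstention()], [tsel_abstention()]
#' @export
abstention_params <- function(p_sel, p_correct, n_outcomes, c, c_T) {
  c <- chk_pos(c, "c"); c_T <- chk_pos(c_T, "c_T"); chk_c_cT(c, c_T)
  new_params(list(
    p_sel = chk_prob(p_sel, "p_sel"),
    p_correct = chk_prob(p_correct, "p_correct"),
    n_outcomes = chk_count(n_outcomes, "n_outcomes", min = 2L),
    c = c, c_T = c_T
  ), "bci_abstention_params")
}

#' Parameters of the general asynchronous scenario
#'
#' The most general speller design: trials may be intended selections or
#' intentional skips (idle periods), the system may abstain or select on
#' either, and dynamic stopping shortens decided trials.  All the other
#' scenarios are special cases of this one.
#'
#' @param pi_sel_i Probability that an intention is a selection (rather than
#'   an intentional skip).
#' @param p_sel_given_sel Probability that the system makes a selection when
#'   a selection is intended.
#' @param p_correct Probability of a correct selection given that a selection
#'   is intended and made.
#' @param p_sel_given_skip Probability that the system (wrongly) makes a
#'   selection when a skip is intended.
#' @param c Expected duration of a decided trial, seconds; `0 < c <= c_T`.
#' @param c_T Duration of a complete trial, seconds.
#' @param b_sel Benefit credited per fulfilled intended selection, in bits
#'   (commonly `log2(N - 1)`, see [benefit_bits()]).
#' @param b_skip Benefit credited per fulfilled intentional skip, in bits.
#' @return An object of class `bci_full_params`.
#' @seealso [utility_full()], [expected_times()], [simulate_process()]
#' @export
#' @examples
#' # the parameters estimated from the worked real-data session
#' full_params(pi_sel_i = 107 / 117, p_sel_given_sel = 94 / 107,
#'             p_correct = 75 / 94, p_sel_given_skip = 2 / 10,
#'             c = 17.21, c_T = 23.192, b_sel = 5.8, b_skip = 5.8)
full_params <- function(pi_sel_i, p_sel_given_sel, p_correct,
                        p_sel_given_skip, c, c_T, b_sel, b_skip) {
  c <- chk_pos(c, "c"); c_T <- chk_pos(c_T, "c_T"); chk_c_cT(c, c_T)
  new_params(list(
    pi_sel_i = chk_prob(pi_sel_i, "pi_sel_i"),
    p_sel_given_sel = chk_prob(p_sel_given_sel, "p_sel_given_sel"),
    p_correct = chk_prob(p_correct, "p_correct"),
    p_sel_given_skip = chk_prob(p_sel_given_skip, "p_sel_given_skip"),
    c = c, c_T = c_T,
    b_sel = chk_nonneg(b_sel, "b_sel"),
    b_skip = chk_nonneg(b_skip, "b_skip")
  ), "bci_full_params")
}

#' @export
print.bci_params <- function(x, ...) {
  scen <- switch(class(x)[1L],
    bci_plain_params = "plain (synchronous) speller",
    bci_dynamic_params = "dynamic stopping",
    bci_abstention_params = "abstention + dynamic stopping",
    bci_full_params = "intentional skip + abstention + dynamic stopping",
    "speller")
  cat("BCI speller parameters:", scen, "\n")
  for (nm in names(x)) cat(sprintf("  %-17s %g\n", nm, x[[nm]]))
  invisible(x)
}

scenario_class <- function(scenario) {
  switch(match.arg(scenario, c("plain", "dynamic", "abstention", "full")),
         plain = "bci_plain_params", dynamic = "bci_dynamic_params",
         abstention = "bci_abstention_params", full = "bci_full_params")
}

scenario_constructor <- function(scenario) {
  switch(match.arg(scenario, c("plain", "dynamic", "abstention", "full")),
         plain = plain_params, dynamic = dynamic_params,
         abstention = abstention_params, full = full_params)
}

#' Read or write a parameter set as a flat key-value config
#'
#' Parameter sets serialize to flat JSON or YAML objects whose keys are the
#' field names of the corresponding constructor (durations in seconds,
#' probabilities as decimals, benefits in bits).  The format is chosen from
#' the file extension (`.json`, or `.yaml`/`.yml`).
#'
#' @param path Path to a `.json`, `.yaml`, or `.yml` file.
#' @param scenario One of `"plain"`, `"dynamic"`, `"abstention"`, `"full"`.
#' @return `read_params()` returns a validated parameter object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path, scenario = c("full", "plain", "dynamic",
                                           "abstention")) {
  scenario <- match.arg(scenario)
  vals <- read_config(path)
  ctor <- scenario_constructor(scenario)
  wanted <- names(formals(ctor))
  missing <- setdiff(wanted, names(vals))
  if (length(missing))
    stop_param("config '", path, "' is missing field(s): ",
               paste(missing, collapse = ", "))
  do.call(ctor, vals[wanted])
}

#' @param params A parameter object created by one of the constructors.
#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "bci_params"))
  write_config(unclass(params), path)
  invisible(path)
}

read_config <- function(path) {
  if (!file.exists(path)) stop_param("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop_param("unsupported config extension '.", ext,
               "' (use .json, .yaml or .yml)")
  }
}

write_config <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else {
    stop_param("unsupported config extension '.", ext,
               "' (use .json, .yaml or .yml)")
  }
  invisible(path)
}
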