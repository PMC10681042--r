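# Parameter sweeps (utility curves) and local sensitivity analysis.

scenario_fields <- list(
  plain = c("p", "n_outcomes", "c_T"),
  dynamic = c("p", "n_outcomes", "c", "c_T"),
  abstention = c("p_sel", "p_correct", "n_outcomes", "c", "c_T"),
  full = c("pi_sel_i", "p_sel_given_sel", "p_correct", "p_sel_given_skip",
           "c", "c_T", "b_sel", "b_skip")
)

scenario_utility <- function(scenario) {
  switch(scenario, plain = utility_plain, dynamic = utility_dynamic,
         abstention = utility_abstention, full = utility_full)
}

#' BCI-Utility curve over a swept parameter
#'
#' Evaluates the closed-form utility of a scenario at each value of one
#' swept parameter, holding the others fixed.  Values outside the valid
#' region are included with utility 0 and regime `"boundary_zero"`, so
#' sweeps across the whole parameter domain never abort.
#'
#' @param scenario One of `"plain"`, `"dynamic"`, `"abstention"`, `"full"`.
#' @param sweep Name of the parameter to sweep (a constructor field of the
#'   scenario, e.g. `"p_correct"`).
#' @param values Ordered vector of values for the swept parameter (may be
#'   empty, giving an empty table).
#' @param fixed Named list with all remaining scenario parameters.
#' @return A data frame with columns `parameter`, `value`, `utility`
#'   (bit/s), and `regime`.
#' @export
#' @examples
#' utility_curve("full", "p_correct", seq(0.55, 0.95, by = 0.1),
#'               fixed = list(pi_sel_i = 0.85, p_sel_given_sel = 0.85,
#'                            p_sel_given_skip = 0.15, c = 14.75,
#'                            c_T = 31.625, b_sel = log2(36),
#'                            b_skip = log2(36)))
utility_curve <- function(scenario = c("plain", "dynamic", "abstention",
                                       "full"),
                          sweep, values, fixed = list()) {
  scenario <- match.arg(scenario)
  fields <- scenario_fields[[scenario]]
  if (!sweep %in% fields)
    stop_param("'", sweep, "' is not a parameter of the ", scenario,
               " scenario (expected one of: ",
               paste(fields, collapse = ", "), ")")
  if (sweep %in% names(fixed))
    stop_param("swept parameter '", sweep, "' must not also be fixed")
  missing <- setdiff(fields, c(sweep, names(fixed)))
  if (length(missing))
    stop_param("missing fixed parameter(s): ",
               paste(missing, collapse = ", "))
  ctor <- scenario_constructor(scenario)
  ufun <- scenario_utility(scenario)
  out <- data.frame(parameter = character(0), value = numeric(0),
                    utility = numeric(0), regime = character(0))
  for (v in values) {
    args <- fixed
    args[[sweep]] <- v
    u <- ufun(do.call(ctor, args[fields]))
    out <- rbind(out, data.frame(parameter = sweep, value = v,
                                 utility = u$value, regime = u$regime))
  }
  out
}

#' Local sensitivity of the BCI-Utility
#'
#' Central finite-difference slopes of the general-scenario utility with
#' respect to each of the five operating parameters (`pi_sel_i`,
#' `p_sel_given_sel`, `p_correct`, `p_sel_given_skip`, `c`), evaluated at a
#' point strictly inside the valid region.  The most sensitive parameter is
#' the most effective one to improve at the current operating point.  Where
#' a symmetric step would leave the parameter's domain, a one-sided
#' difference is used with a warning.
#'
#' @param params A [full_params()] object strictly inside the valid region.
#' @param step_prob Step for the probability parameters.
#' @param step_dur Step for the duration parameter `c`, seconds.
#' @return A data frame with columns `parameter`, `slope` (bit/s per unit
#'   of the parameter), and `method` (`"central"` or one-sided).
#' @export
sensitivity <- function(params, step_prob = 1e-4, step_dur = 1e-2) {
  stopifnot(inherits(params, "bci_full_params"))
  if (params$p_correct <= 0.5 || params$p_sel_given_sel <= 0 ||
      params$p_sel_given_skip >= 1)
    stop_param("'params' must lie strictly inside the valid region")
  u_at <- function(name, value) {
    p <- unclass(params)
    p[[name]] <- value
    utility_full(do.call(full_params, p))$value
  }
  # open bounds nudged so the evaluation stays inside the valid region
  domain <- list(
    pi_sel_i = c(0, 1),
    p_sel_given_sel = c(1e-12, 1),
    p_correct = c(0.5 + 1e-12, 1),
    p_sel_given_skip = c(0, 1 - 1e-12),
    c = c(1e-12, params$c_T)
  )
  out <- lapply(names(domain), function(nm) {
    h <- if (nm == "c") step_dur else step_prob
    x <- params[[nm]]
    lo <- domain[[nm]][1]; hi <- domain[[nm]][2]
    if (x - h >= lo && x + h <= hi) {
      slope <- (u_at(nm, x + h) - u_at(nm, x - h)) / (2 * h)
      method <- "central"
    } else if (x + h <= hi) {
      warning("one-sided (forward) difference for '", nm,
              "': parameter too close to its lower bound")
      slope <- (u_at(nm, x + h) - u_at(nm, x)) / h
      method <- "forward"
    } else {
      warning("one-sided (backward) difference for '", nm,
              "': parameter too close to its upper bound")
      slope <- (u_at(nm, x) - u_at(nm, x - h)) / h
      method <- "backward"
    }
    data.frame(parameter = nm, slope = slope, method = method)
  })
  do.call(rbind, out)
}
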