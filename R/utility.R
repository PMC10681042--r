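#' Information benefit of a selection
#'
#' Benefit, in bits, conveyed by one selection on a keyboard with
#' `n_outcomes` possible trial outcomes (`n_outcomes - 1` characters plus a
#' backspace), assuming all characters are equally probable:
#' `log2(n_outcomes - 1)`.
#'
#' @param n_outcomes Number of possible outcomes per trial; at least 2.
#'   Vectorized.
#' @return Benefit in bits.
#' @export
#' @examples
#' benefit_bits(37)   # row-column paradigm with a skip outcome: log2(36)
benefit_bits <- function(n_outcomes) {
  if (!is.numeric(n_outcomes) || length(n_outcomes) == 0L ||
      anyNA(n_outcomes) || any(n_outcomes < 2))
    stop_param("'n_outcomes' must be numeric with all values >= 2")
  log2(n_outcomes - 1)
}

#' Average per-trial benefit for variable keyboard sizes
#'
#' When the number of on-screen keys varies across trials, the session-level
#' benefit is the arithmetic mean of `log2(keyboard_size)` over trials.
#'
#' @param keyboard_sizes Per-trial counts of on-screen keys; all at least 2.
#' @return Mean benefit in bits.
#' @export
#' @examples
#' average_benefit(c(49, 69))
average_benefit <- function(keyboard_sizes) {
  if (length(keyboard_sizes) == 0L)
    stop_param("'keyboard_sizes' must be non-empty")
  if (!is.numeric(keyboard_sizes) || anyNA(keyboard_sizes) ||
      any(keyboard_sizes < 2))
    stop_param("'keyboard_sizes' must all be >= 2")
  mean(log2(keyboard_sizes))
}

new_utility <- function(value, regime = c("valid", "boundary_zero")) {
  regime <- match.arg(regime)
  structure(list(value = value, regime = regime), class = "bci_utility")
}

#' @export
print.bci_utility <- function(x, ...) {
  cat(sprintf("BCI-Utility: %.5g bit/s", x$value))
  if (x$regime == "boundary_zero")
    cat("  (outside the valid region; expected times diverge)")
  cat("\n")
  invisible(x)
}

#' @export
as.double.bci_utility <- function(x, ...) x$value

divergent <- function(why) {
  warning(warningCondition(
    paste0("expected time diverges: ", why),
    class = "bci_divergence_warning"))
  Inf
}

#' BCI-Utility of a plain synchronous speller
#'
#' For accuracy `p > 0.5` the metric is
#' `U = (2 p - 1) log2(N - 1) / c_T` bits per second; for `p <= 0.5` the
#' expected time to produce a correct selection diverges and the metric is
#' defined as zero (regime `"boundary_zero"`).
#'
#' @param params A [plain_params()] object.
#' @return A `bci_utility` object with fields `value` (bit/s) and `regime`.
#' @export
#' @examples
#' utility_plain(plain_params(p = 0.9, n_outcomes = 37, c_T = 31.625))
utility_plain <- function(params) {
  stopifnot(inherits(params, "bci_plain_params"))
  if (params$p <= 0.5) return(new_utility(0, "boundary_zero"))
  new_utility((2 * params$p - 1) * benefit_bits(params$n_outcomes) /
                params$c_T)
}

#' BCI-Utility with dynamic stopping
#'
#' Same form as [utility_plain()] with the expected decided-trial duration
#' `c` in place of the complete-trial duration `c_T`:
#' `U = (2 p - 1) log2(N - 1) / c` for `p > 0.5`, else zero.  With `c = c_T`
#' (dynamic stopping disabled) this reduces exactly to the plain formula.
#'
#' @param params A [dynamic_params()] object.
#' @inherit utility_plain return
#' @export
utility_dynamic <- function(params) {
  stopifnot(inherits(params, "bci_dynamic_params"))
  if (params$p <= 0.5) return(new_utility(0, "boundary_zero"))
  new_utility((2 * params$p - 1) * benefit_bits(params$n_outcomes) /
                params$c)
}

#' Expected selection time with abstention and dynamic stopping
#'
#' Expected time to fulfil an intended selection (equal to the expected time
#' to type a backspace):
#' `(p_sel c + (1 - p_sel) c_T) / (p_sel (2 p_correct - 1))`.
#' Diverges (returns `Inf` with a warning) when `p_correct <= 0.5` or
#' `p_sel = 0`.
#'
#' @param params An [abstention_params()] object.
#' @return Expected time in seconds, possibly `Inf`.
#' @export
tsel_abstention <- function(params) {
  stopifnot(inherits(params, "bci_abstention_params"))
  if (params$p_correct <= 0.5)
    return(divergent("p_correct <= 0.5"))
  if (params$p_sel == 0)
    return(divergent("p_sel = 0"))
  (params$p_sel * params$c + (1 - params$p_sel) * params$c_T) /
    (params$p_sel * (2 * params$p_correct - 1))
}

#' BCI-Utility with abstention and dynamic stopping
#'
#' `U = log2(N - 1) / Tsel` where `Tsel` is [tsel_abstention()]; zero
#' (regime `"boundary_zero"`) when `p_correct <= 0.5` or `p_sel = 0`.
#'
#' @inheritParams tsel_abstention
#' @inherit utility_plain return
#' @export
utility_abstention <- function(params) {
  stopifnot(inherits(params, "bci_abstention_params"))
  if (params$p_correct <= 0.5 || params$p_sel == 0)
    return(new_utility(0, "boundary_zero"))
  new_utility(benefit_bits(params$n_outcomes) / tsel_abstention(params))
}

#' Expected times in the general scenario
#'
#' Closed-form expected times for the general asynchronous speller.
#' `tsel_full()` is the expected time to fulfil an intended selection and
#' also the expected time to type a backspace (`Tsel = Tbs`):
#' `(p_sel_given_sel c + (1 - p_sel_given_sel) c_T) /
#'  (p_sel_given_sel (2 p_correct - 1))`.
#' `tskip_full()` is the expected time to fulfil an intentional skip:
#' `(p_sel_given_skip (c + Tbs) + (1 - p_sel_given_skip) c_T) /
#'  (1 - p_sel_given_skip)`.
#' Each returns `Inf` with a warning where the corresponding expectation
#' diverges (`p_correct <= 0.5` or `p_sel_given_sel = 0`;
#' `p_sel_given_skip = 1`).
#'
#' @param params A [full_params()] object.
#' @param t_bs Expected backspace time in seconds; defaults to
#'   `tsel_full(params)`.
#' @return Expected time in seconds, possibly `Inf`.
#' @export
#' @examples
#' pars <- full_params(107 / 117, 94 / 107, 75 / 94, 2 / 10,
#'                     c = 17.21, c_T = 23.192, b_sel = 5.8, b_skip = 5.8)
#' tsel_full(pars)    # 34.27 s
#' tskip_full(pars)   # 36.06 s
tsel_full <- function(params) {
  stopifnot(inherits(params, "bci_full_params"))
  if (params$p_correct <= 0.5)
    return(divergent("p_correct <= 0.5"))
  if (params$p_sel_given_sel == 0)
    return(divergent("p_sel_given_sel = 0"))
  (params$p_sel_given_sel * params$c +
     (1 - params$p_sel_given_sel) * params$c_T) /
    (params$p_sel_given_sel * (2 * params$p_correct - 1))
}

#' @rdname tsel_full
#' @export
tskip_full <- function(params, t_bs = tsel_full(params)) {
  stopifnot(inherits(params, "bci_full_params"))
  if (params$p_sel_given_skip == 1)
    return(divergent("p_sel_given_skip = 1"))
  if (!is.finite(t_bs))
    return(divergent("backspace time t_bs is not finite"))
  (params$p_sel_given_skip * (params$c + t_bs) +
     (1 - params$p_sel_given_skip) * params$c_T) /
    (1 - params$p_sel_given_skip)
}

#' @rdname tsel_full
#' @return `expected_times()` returns a list of class `bci_times` with
#'   fields `t_sel`, `t_bs`, and `t_skip` (seconds).
#' @export
expected_times <- function(params) {
  stopifnot(inherits(params, "bci_full_params"))
  valid <- params$p_correct > 0.5 && params$p_sel_given_sel > 0 &&
    params$p_sel_given_skip < 1
  if (!valid) {
    t_sel <- suppressWarnings(tsel_full(params))
    t_skip <- suppressWarnings(tskip_full(params, t_bs = t_sel))
  } else {
    t_sel <- tsel_full(params)
    t_skip <- tskip_full(params, t_bs = t_sel)
  }
  structure(list(t_sel = t_sel, t_bs = t_sel, t_skip = t_skip),
            class = "bci_times")
}

#' @export
print.bci_times <- function(x, ...) {
  cat(sprintf("Expected times (s): Tsel = Tbs = %.4g, Tskip = %.4g\n",
              x$t_sel, x$t_skip))
  invisible(x)
}

#' BCI-Utility of the general asynchronous speller
#'
#' In the valid region (`p_correct > 0.5`, `p_sel_given_sel > 0`,
#' `p_sel_given_skip < 1`),
#' `U = (pi_sel_i b_sel + (1 - pi_sel_i) b_skip) /
#'      (pi_sel_i Tsel + (1 - pi_sel_i) Tskip)`
#' with `Tsel`, `Tskip` from [expected_times()].  Outside the valid region
#' the expected times diverge and the metric is zero (regime
#' `"boundary_zero"`).
#'
#' @inheritParams tsel_full
#' @inherit utility_plain return
#' @export
#' @examples
#' pars <- full_params(107 / 117, 94 / 107, 75 / 94, 2 / 10,
#'                     c = 17.21, c_T = 23.192, b_sel = 5.8, b_skip = 5.8)
#' utility_full(pars)   # about 0.168 bit/s
utility_full <- function(params) {
  stopifnot(inherits(params, "bci_full_params"))
  if (params$p_correct <= 0.5 || params$p_sel_given_sel == 0 ||
      params$p_sel_given_skip == 1)
    return(new_utility(0, "boundary_zero"))
  tt <- expected_times(params)
  pi1 <- params$pi_sel_i
  new_utility((pi1 * params$b_sel + (1 - pi1) * params$b_skip) /
                (pi1 * tt$t_sel + (1 - pi1) * tt$t_skip))
}
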