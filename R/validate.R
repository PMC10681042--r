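# Replication of the three validating simulation studies: the full-grid
# scatter validation, the per-combination mean/SD study, and the
# assumption-violation experiment with decaying accuracy.

# Vectorized closed form; returns 0 where the valid region
# (p_correct > 0.5, p_sel_given_sel > 0, p_sel_given_skip < 1) is left.
u_formula_vec <- function(pi_sel_i, p_sel_given_sel, p_correct,
                          p_sel_given_skip, c, c_T, b_sel, b_skip) {
  t_sel <- (p_sel_given_sel * c + (1 - p_sel_given_sel) * c_T) /
    (p_sel_given_sel * (2 * p_correct - 1))
  t_skip <- (p_sel_given_skip * (c + t_sel) +
               (1 - p_sel_given_skip) * c_T) / (1 - p_sel_given_skip)
  u <- (pi_sel_i * b_sel + (1 - pi_sel_i) * b_skip) /
    (pi_sel_i * t_sel + (1 - pi_sel_i) * t_skip)
  invalid <- p_correct <= 0.5 | p_sel_given_sel == 0 | p_sel_given_skip == 1
  u[invalid] <- 0
  u
}

#' Simulation-study parameter grid
#'
#' `table1_values()` returns the grid of probability values used in the
#' validating simulation study: 38 values of `pi_sel_i`, 28 of
#' `p_sel_given_skip`, 28 of `p_sel_given_sel`, and 28 of `p_correct`, with
#' finer steps in the high-performance ranges.  `table1_grid()` expands them
#' into the full Cartesian product of 38 x 28 x 28 x 28 = 834,176 parameter
#' tuples, ordered lexicographically in that parameter order.
#'
#' @param values A named list of value vectors for `pi_sel_i`,
#'   `p_sel_given_skip`, `p_sel_given_sel`, and `p_correct`.
#' @return `table1_values()`: a named list of numeric vectors.
#'   `table1_grid()`: a data frame with one row per tuple.
#' @export
table1_values <- function() {
  list(
    pi_sel_i = c(seq(0, 0.7, by = 0.1), seq(0.71, 1, by = 0.01)),
    p_sel_given_skip = c(seq(0, 0.19, by = 0.01), seq(0.2, 0.9, by = 0.1)),
    p_sel_given_sel = c(seq(0.1, 0.8, by = 0.1), seq(0.81, 1, by = 0.01)),
    p_correct = c(seq(0.55, 0.75, by = 0.1), seq(0.76, 1, by = 0.01))
  )
}

#' @rdname table1_values
#' @export
table1_grid <- function(values = table1_values()) {
  wanted <- c("pi_sel_i", "p_sel_given_skip", "p_sel_given_sel", "p_correct")
  if (!is.list(values) || !all(wanted %in% names(values)))
    stop_param("'values' must be a named list with elements: ",
               paste(wanted, collapse = ", "))
  for (nm in wanted) {
    v <- values[[nm]]
    if (!is.numeric(v) || length(v) == 0L || anyNA(v) ||
        any(v < 0 | v > 1))
      stop_param("grid values for '", nm, "' must be probabilities")
  }
  # expand.grid varies the first factor fastest; reverse so the first listed
  # parameter varies slowest (lexicographic order)
  g <- expand.grid(p_correct = values$p_correct,
                   p_sel_given_sel = values$p_sel_given_sel,
                   p_sel_given_skip = values$p_sel_given_skip,
                   pi_sel_i = values$pi_sel_i,
                   KEEP.OUT.ATTRS = FALSE)
  g[, rev(seq_along(g)), drop = FALSE]
}

#' Scatter validation of the closed form against simulation
#'
#' For each parameter tuple, computes the closed-form BCI-Utility and the
#' observed average benefit of one simulated process of `k_intentions`
#' intended outcomes, at the study conditions `c = 14.75` s,
#' `c_T = 31.625` s and benefits `log2(36)` bits.  The ergodic theorem makes
#' the observed values concentrate on the diagonal.
#'
#' @param tuples Data frame of parameter tuples with columns `pi_sel_i`,
#'   `p_sel_given_skip`, `p_sel_given_sel`, `p_correct` (for example a
#'   subsample of [table1_grid()] rows).
#' @param k_intentions Intended outcomes per simulated process.
#' @param seed Seed set once before the sweep.
#' @param c,c_T Expected decided-trial / complete-trial durations, seconds.
#' @param b_sel,b_skip Benefits in bits.
#' @param boundary How to treat tuples outside the valid region, where the
#'   observed process cannot be simulated: `"zero"` keeps the row with
#'   `u_formula = 0` and `u_observed = NA`; `"skip"` drops it.
#' @param max_events Divergence guard per intention.
#' @return The input tuples with columns `u_formula` and `u_observed`
#'   (bit/s) appended.
#' @export
scatter_validation <- function(tuples, k_intentions = 5000L, seed = 1L,
                               c = 14.75, c_T = 31.625,
                               b_sel = log2(36), b_skip = log2(36),
                               boundary = c("zero", "skip"),
                               max_events = 1e6) {
  boundary <- match.arg(boundary)
  wanted <- c("pi_sel_i", "p_sel_given_skip", "p_sel_given_sel", "p_correct")
  if (!is.data.frame(tuples) || !all(wanted %in% names(tuples)))
    stop_param("'tuples' must have columns: ", paste(wanted, collapse = ", "))
  set.seed(seed)
  u_formula <- u_formula_vec(tuples$pi_sel_i, tuples$p_sel_given_sel,
                             tuples$p_correct, tuples$p_sel_given_skip,
                             c, c_T, b_sel, b_skip)
  valid <- tuples$p_correct > 0.5 & tuples$p_sel_given_sel > 0 &
    tuples$p_sel_given_skip < 1
  if (boundary == "skip") {
    tuples <- tuples[valid, , drop = FALSE]
    u_formula <- u_formula[valid]
    valid <- rep(TRUE, nrow(tuples))
  }
  u_observed <- rep(NA_real_, nrow(tuples))
  for (i in seq_len(nrow(tuples))) {
    if (!valid[i]) next
    kind <- stats::runif(k_intentions) < tuples$pi_sel_i[i]
    eng <- sim_chains(kind, tuples$p_sel_given_sel[i], tuples$p_correct[i],
                      tuples$p_sel_given_skip[i], max_events)
    n_dec <- eng$n_seltask_dec + eng$n_skipatt_dec
    n_com <- (eng$n_seltask + eng$n_skipatt) - n_dec
    u_observed[i] <- sum(ifelse(kind, b_sel, b_skip)) /
      sum(n_dec * c + n_com * c_T)
  }
  out <- tuples
  out$u_formula <- u_formula
  out$u_observed <- u_observed
  out
}

#' Parameter combinations of the mean/SD study
#'
#' The 20 parameter combinations at which the spread of the observed average
#' benefit was studied: one base combination and sweeps of each of the four
#' probabilities around it.
#'
#' @return A data frame with columns `pi_sel_i`, `p_sel_given_skip`,
#'   `p_sel_given_sel`, `p_correct`.
#' @export
table2_combos <- function() {
  base <- list(pi_sel_i = 0.85, p_sel_given_skip = 0.15,
               p_sel_given_sel = 0.85, p_correct = 0.85)
  sweep1 <- function(name, values) {
    g <- base
    do.call(rbind, lapply(values, function(v) {
      g[[name]] <- v
      as.data.frame(g)
    }))
  }
  rbind(sweep1("pi_sel_i", seq(0.75, 0.95, by = 0.05)),
        sweep1("p_sel_given_skip", seq(0.05, 0.25, by = 0.05)),
        sweep1("p_sel_given_sel", seq(0.75, 0.95, by = 0.05)),
        sweep1("p_correct", seq(0.75, 0.95, by = 0.05)))
}

#' Mean and SD of the observed average benefit per combination
#'
#' For each parameter combination, simulates `n_processes` independent
#' processes of `k_intentions` intended outcomes at the study conditions and
#' reports the sample mean and sample standard deviation (n - 1 denominator)
#' of the observed average benefit, together with the closed-form value.
#'
#' @param combos Data frame of parameter combinations (see
#'   [table2_combos()]).
#' @param n_processes Processes per combination (at least 2).
#' @inheritParams scatter_validation
#' @return A data frame with the combination parameters and columns
#'   `mean_uk`, `sd_uk`, `n`, and `u_formula` (all in bit/s).
#' @export
table2_replication <- function(combos = table2_combos(),
                               n_processes = 1000L, k_intentions = 5000L,
                               seed = 1L, c = 14.75, c_T = 31.625,
                               b_sel = log2(36), b_skip = log2(36)) {
  if (n_processes < 2L)
    stop_param("'n_processes' must be at least 2 to estimate an SD")
  set.seed(seed)
  out <- combos
  out$mean_uk <- out$sd_uk <- NA_real_
  for (i in seq_len(nrow(combos))) {
    pars <- full_params(combos$pi_sel_i[i], combos$p_sel_given_sel[i],
                        combos$p_correct[i], combos$p_sel_given_skip[i],
                        c = c, c_T = c_T, b_sel = b_sel, b_skip = b_skip)
    uk <- simulate_processes(pars, n_processes, k_intentions)$uk
    out$mean_uk[i] <- mean(uk)
    out$sd_uk[i] <- stats::sd(uk)
  }
  out$n <- n_processes
  out$u_formula <- u_formula_vec(combos$pi_sel_i, combos$p_sel_given_sel,
                                 combos$p_correct, combos$p_sel_given_skip,
                                 c, c_T, b_sel, b_skip)
  out
}

#' Configuration of the assumption-violation experiment
#'
#' Describes a non-stationary process that violates the time-independence
#' and memorylessness assumptions: all three accuracies (`p_correct`,
#' `p_sel_given_sel`, `p_skip_given_skip`) start at `initial_accuracy` and
#' decay linearly with the number of intentions, while the expected
#' decided-trial duration grows linearly from `c_initial`, capped at
#' `c_max`.  After any wrong system action (a wrong selection, an abstention
#' when a selection was intended, or a selection when a skip was intended),
#' the single next intention reverts to the initial values; decay then
#' resumes at the global intention index (`decay_reference = "global"`, the
#' default) or restarts counting from the mistake
#' (`decay_reference = "since_reset"`).  The intention pattern is 20
#' intended selections followed by 5 intentional skips, repeated 4 times
#' (100 intentions).
#'
#' @param initial_accuracy Accuracy at a fresh (or just-reset) intention.
#' @param accuracy_decay_per_intention Linear decay per intention.
#' @param c_initial,c_increment_per_intention,c_max Expected decided-trial
#'   duration: start, per-intention increment, and cap, seconds.
#' @param c_T Complete-trial duration, seconds (also the cap default).
#' @param intention_pattern Logical vector, `TRUE` for an intended
#'   selection.
#' @param b_sel,b_skip Benefits in bits.
#' @param decay_reference `"global"` (decay follows the global intention
#'   index) or `"since_reset"` (decay restarts after each mistake).
#' @param max_events Divergence guard per intention.
#' @return A list of class `bci_violation_config`.
#' @export
violation_config <- function(initial_accuracy = 0.90,
                             accuracy_decay_per_intention = 0.002,
                             c_initial = 14.75,
                             c_increment_per_intention = 0.2,
                             c_max = 31.625, c_T = 31.625,
                             intention_pattern =
                               rep(c(rep(TRUE, 20), rep(FALSE, 5)), 4),
                             b_sel = log2(36), b_skip = log2(36),
                             decay_reference = c("global", "since_reset"),
                             max_events = 1e6) {
  structure(list(
    initial_accuracy = chk_prob(initial_accuracy, "initial_accuracy"),
    accuracy_decay_per_intention =
      chk_nonneg(accuracy_decay_per_intention,
                 "accuracy_decay_per_intention"),
    c_initial = chk_pos(c_initial, "c_initial"),
    c_increment_per_intention =
      chk_nonneg(c_increment_per_intention, "c_increment_per_intention"),
    c_max = chk_pos(c_max, "c_max"),
    c_T = chk_pos(c_T, "c_T"),
    intention_pattern = as.logical(intention_pattern),
    b_sel = chk_nonneg(b_sel, "b_sel"),
    b_skip = chk_nonneg(b_skip, "b_skip"),
    decay_reference = match.arg(decay_reference),
    max_events = chk_count(max_events, "max_events")
  ), class = "bci_violation_config")
}

# Simulates n_processes non-stationary processes in parallel, one intention
# step at a time.  Returns per-intention record matrices (processes x
# intentions).
#
# Decay is indexed by the global intention count: intention t (1-based) uses
# j = t - 1 decay steps, except that the single intention following a
# mistake reverts to the initial values (j = 0).  With
# decay_reference = "since_reset" the index instead counts intentions since
# the last mistake.
sim_violation <- function(config, n_processes) {
  pat <- config$intention_pattern
  k <- length(pat)
  n <- n_processes
  mat <- function() matrix(0, nrow = n, ncol = k)
  m <- list(delta_t = mat(), benefit = mat(), t_decided = mat(),
            n_decided = mat(), n_complete = mat(),
            n_seltask = mat(), n_seltask_dec = mat(), n_wrong = mat(),
            n_skipatt = mat(), n_skipatt_dec = mat())
  since_reset <- identical(config$decay_reference, "since_reset")
  j_reset <- integer(n)     # intentions since the last mistake
  revert <- logical(n)      # previous intention had a mistake
  for (t in seq_len(k)) {
    j <- if (since_reset) j_reset else ifelse(revert, 0L, t - 1L)
    acc <- pmin(1, pmax(0, config$initial_accuracy -
                          config$accuracy_decay_per_intention * j))
    c_t <- pmin(config$c_max,
                config$c_initial + config$c_increment_per_intention * j)
    eng <- sim_chains(rep(pat[t], n), p_sel_given_sel = acc,
                      p_correct = acc, p_sel_given_skip = 1 - acc,
                      max_events = config$max_events)
    n_dec <- eng$n_seltask_dec + eng$n_skipatt_dec
    n_com <- (eng$n_seltask + eng$n_skipatt) - n_dec
    m$t_decided[, t] <- n_dec * c_t
    m$delta_t[, t] <- n_dec * c_t + n_com * config$c_T
    m$benefit[, t] <- if (pat[t]) config$b_sel else config$b_skip
    m$n_decided[, t] <- n_dec
    m$n_complete[, t] <- n_com
    m$n_seltask[, t] <- eng$n_seltask
    m$n_seltask_dec[, t] <- eng$n_seltask_dec
    m$n_wrong[, t] <- eng$n_wrong
    m$n_skipatt[, t] <- eng$n_skipatt
    m$n_skipatt_dec[, t] <- eng$n_skipatt_dec
    mistake <- eng$n_wrong + (eng$n_seltask - eng$n_seltask_dec) +
      eng$n_skipatt_dec > 0L
    j_reset <- ifelse(mistake, 0L, j_reset + 1L)
    revert <- mistake
  }
  m
}

#' Simulate one non-stationary process
#'
#' @param config A [violation_config()].
#' @param seed Integer seed.
#' @return A `bci_process` whose records carry the same columns as
#'   [simulate_process()].  With the decay and increment rates set to zero
#'   the process is statistically identical to the stationary model.
#' @export
violation_process <- function(config, seed = 1L) {
  stopifnot(inherits(config, "bci_violation_config"))
  set.seed(seed)
  m <- sim_violation(config, 1L)
  pat <- config$intention_pattern
  records <- data.frame(
    index = seq_along(pat),
    intended_kind = ifelse(pat, "selection", "skip"),
    delta_t = drop(m$delta_t),
    benefit = drop(m$benefit),
    n_trials = drop(m$n_seltask + m$n_skipatt),
    n_backspaces = drop(m$n_wrong + m$n_skipatt_dec),
    n_system_errors = drop(m$n_wrong + (m$n_seltask - m$n_seltask_dec) +
                             m$n_skipatt_dec),
    n_decided_trials = drop(m$n_decided),
    n_complete_trials = drop(m$n_complete),
    n_seltask_trials = drop(m$n_seltask),
    n_seltask_decided = drop(m$n_seltask_dec),
    n_wrong_selections = drop(m$n_wrong),
    n_skipatt_trials = drop(m$n_skipatt),
    n_skipatt_decided = drop(m$n_skipatt_dec),
    t_decided = drop(m$t_decided)
  )
  structure(list(records = records, k_intentions = length(pat),
                 seed = seed, config = config,
                 params = NULL),
            class = "bci_process")
}

# Segment-wise empirical estimates and the corresponding closed-form value,
# vectorized over processes.  Sums are per-process totals over the segment.
segment_utility <- function(s, c_T_fallback, b_sel, b_skip) {
  pi_hat <- ifelse(s$n_int > 0, s$n_sel_int / s$n_int, NA_real_)
  pss_hat <- ifelse(s$n_seltask > 0, s$n_seltask_dec / s$n_seltask,
                    NA_real_)
  pc_hat <- ifelse(s$n_seltask_dec > 0,
                   (s$n_seltask_dec - s$n_wrong) / s$n_seltask_dec,
                   NA_real_)
  pks_hat <- ifelse(s$n_skipatt > 0, s$n_skipatt_dec / s$n_skipatt,
                    NA_real_)
  # with no intentional skips in the segment the skip terms carry weight 0
  pks_hat[is.na(pks_hat) & !is.na(pi_hat) & pi_hat == 1] <- 0
  c_hat <- ifelse(s$n_decided > 0, s$t_decided / s$n_decided, NA_real_)
  c_T_hat <- ifelse(s$n_complete > 0,
                    (s$delta_t - s$t_decided) / s$n_complete, c_T_fallback)
  u <- u_formula_vec(pi_hat, pss_hat, pc_hat, pks_hat, c_hat, c_T_hat,
                     b_sel, b_skip)
  u[is.na(pi_hat) | is.na(pss_hat) | is.na(pc_hat) | is.na(pks_hat) |
      is.na(c_hat)] <- NA_real_
  u
}

segment_sums <- function(m, pat, cols) {
  sub <- function(x) rowSums(x[, cols, drop = FALSE])
  list(n_int = length(cols), n_sel_int = sum(pat[cols]),
       n_seltask = sub(m$n_seltask), n_seltask_dec = sub(m$n_seltask_dec),
       n_wrong = sub(m$n_wrong), n_skipatt = sub(m$n_skipatt),
       n_skipatt_dec = sub(m$n_skipatt_dec),
       n_decided = sub(m$n_decided), n_complete = sub(m$n_complete),
       t_decided = sub(m$t_decided), delta_t = sub(m$delta_t))
}

violation_summaries <- function(m, config) {
  pat <- config$intention_pattern
  k <- length(pat)
  first <- seq_len(k %/% 2)
  second <- setdiff(seq_len(k), first)
  u_seg <- function(cols)
    segment_utility(segment_sums(m, pat, cols), config$c_T,
                    config$b_sel, config$b_skip)
  u_first <- u_seg(first)
  u_second <- u_seg(second)
  data.frame(
    u_observed = rowSums(m$benefit) / rowSums(m$delta_t),
    u_all = u_seg(seq_len(k)),
    u_first_half = u_first,
    u_second_half = u_second,
    u_mean_of_halves = (u_first + u_second) / 2
  )
}

#' Segment-wise utility estimates for one process
#'
#' Estimates the metric parameters empirically from the event records of a
#' process (all intentions, the first half, and the second half of the
#' intentions, split by intention index), applies the closed-form utility to
#' each set of estimates, and compares with the observed average benefit.
#' Under non-stationary decay the first half overestimates and the second
#' half underestimates the observed value.
#'
#' @param process A `bci_process` with at least 4 intentions (from
#'   [violation_process()] or [simulate_process()]).
#' @param c_T_fallback Complete-trial duration used when a segment contains
#'   no completed trial.
#' @param b_sel,b_skip Benefits in bits.
#' @return A one-row data frame with `u_observed`, `u_all`, `u_first_half`,
#'   `u_second_half`, `u_mean_of_halves` (bit/s; `NA` where a segment lacks
#'   the events needed to estimate a parameter).
#' @export
violation_estimates <- function(process, c_T_fallback = NULL,
                                b_sel = NULL, b_skip = NULL) {
  stopifnot(inherits(process, "bci_process"))
  r <- process$records
  if (nrow(r) < 4L)
    stop_param("need at least 4 intentions to split into halves")
  cfg <- process$config
  if (is.null(c_T_fallback))
    c_T_fallback <- if (!is.null(cfg)) cfg$c_T else process$params$c_T
  if (is.null(b_sel))
    b_sel <- if (!is.null(cfg)) cfg$b_sel else process$params$b_sel
  if (is.null(b_skip))
    b_skip <- if (!is.null(cfg)) cfg$b_skip else process$params$b_skip
  pat <- r$intended_kind == "selection"
  m <- list(n_seltask = t(r$n_seltask_trials),
            n_seltask_dec = t(r$n_seltask_decided),
            n_wrong = t(r$n_wrong_selections),
            n_skipatt = t(r$n_skipatt_trials),
            n_skipatt_dec = t(r$n_skipatt_decided),
            n_decided = t(r$n_decided_trials),
            n_complete = t(r$n_complete_trials),
            t_decided = t(r$t_decided),
            delta_t = t(r$delta_t),
            benefit = t(r$benefit))
  cfg <- list(intention_pattern = pat, c_T = c_T_fallback,
              b_sel = b_sel, b_skip = b_skip)
  violation_summaries(m, cfg)
}

#' Replicated assumption-violation experiment
#'
#' Simulates many non-stationary processes and returns the per-process
#' observed average benefit together with the closed-form utility computed
#' from parameters estimated over all intentions, each half, and the mean of
#' the halves.
#'
#' @inheritParams violation_process
#' @param n_processes Number of replicated processes.
#' @return A data frame with one row per process (columns as in
#'   [violation_estimates()]).
#' @export
violation_experiment <- function(config = violation_config(),
                                 n_processes = 1000L, seed = 1L) {
  stopifnot(inherits(config, "bci_violation_config"))
  set.seed(seed)
  m <- sim_violation(config, n_processes)
  violation_summaries(m, config)
}
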