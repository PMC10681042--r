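# Discrete-event simulation of asynchronous speller usage.
#
# Every chain fulfils one intention.  State per chain is an explicit counter
# of pending selection-type tasks (the intended character plus any backspaces
# owed for wrong selections) and a flag for an open intentional skip.  One
# trial is realized per step:
#   pending > 0 (a selection is intended, character or backspace):
#     u < pss*pc        correct selection  -> pending - 1, decided trial (c)
#     u < pss           wrong selection    -> pending + 1, decided trial (c)
#     otherwise         system abstains    -> complete trial (c_T)
#   pending == 0, skip open (an intentional skip is pending):
#     u < pks           system selects     -> pending + 1 (backspace owed),
#                                             decided trial (c)
#     otherwise         system abstains    -> skip fulfilled, complete trial
# A wrong selection during a backspace leaves two backspaces owed, which the
# pending counter represents without recursion.

divergence_error <- function(max_events) {
  stop(errorCondition(
    paste0("intention not fulfilled within ", max_events, " trials; the ",
           "expected fulfilment time likely diverges (p_correct <= 0.5 or ",
           "p_sel_given_skip = 1)"),
    class = c("bci_divergence_error", "error")))
}

# Core engine: one call realizes length(kind_sel) independent chains.
# Probabilities may be scalars or per-chain vectors.  Returns per-chain
# integer event counts; durations are attached by the callers.
sim_chains <- function(kind_sel, p_sel_given_sel, p_correct,
                       p_sel_given_skip, max_events = 1e6) {
  n <- length(kind_sel)
  pss <- rep_len(as.numeric(p_sel_given_sel), n)
  pc <- rep_len(as.numeric(p_correct), n)
  pks <- rep_len(as.numeric(p_sel_given_skip), n)

  pending <- as.integer(kind_sel)
  skip_open <- !kind_sel
  n_seltask <- integer(n)       # trials while a selection-type task pending
  n_seltask_dec <- integer(n)   # ... of which produced a selection
  n_wrong <- integer(n)         # wrong selections among those
  n_skipatt <- integer(n)       # skip attempts (trials with skip pending)
  n_skipatt_dec <- integer(n)   # ... of which the system wrongly selected
  events <- integer(n)

  idx <- which(pending > 0L | skip_open)
  while (length(idx)) {
    u <- stats::runif(length(idx))
    selphase <- pending[idx] > 0L
    p1 <- pss[idx]

    made <- selphase & u < p1
    corr <- made & u < p1 * pc[idx]
    wrong <- made & !corr
    skipatt <- !selphase
    skipdec <- skipatt & u < pks[idx]
    skipok <- skipatt & !skipdec

    i <- idx[corr];    pending[i] <- pending[i] - 1L
    i <- idx[wrong];   pending[i] <- pending[i] + 1L
    i <- idx[skipdec]; pending[i] <- pending[i] + 1L
    skip_open[idx[skipok]] <- FALSE

    i <- idx[selphase]; n_seltask[i] <- n_seltask[i] + 1L
    i <- idx[made];     n_seltask_dec[i] <- n_seltask_dec[i] + 1L
    i <- idx[wrong];    n_wrong[i] <- n_wrong[i] + 1L
    i <- idx[skipatt];  n_skipatt[i] <- n_skipatt[i] + 1L
    i <- idx[skipdec];  n_skipatt_dec[i] <- n_skipatt_dec[i] + 1L
    events[idx] <- events[idx] + 1L

    idx <- idx[pending[idx] > 0L | skip_open[idx]]
    if (length(idx) && any(events[idx] >= max_events))
      divergence_error(max_events)
  }

  list(kind_sel = kind_sel,
       n_seltask = n_seltask, n_seltask_dec = n_seltask_dec,
       n_wrong = n_wrong,
       n_skipatt = n_skipatt, n_skipatt_dec = n_skipatt_dec)
}

# Trial durations for simulated chains.  Deterministic by default: c per
# decided trial, c_T per completed (abstained) trial.  A stochastic duration
# model supplies r_decided(n)/r_complete(n) samplers with means c and c_T.
chain_times <- function(eng, c, c_T, duration_model = NULL) {
  n <- length(eng$kind_sel)
  n_dec <- eng$n_seltask_dec + eng$n_skipatt_dec
  n_com <- (eng$n_seltask - eng$n_seltask_dec) +
    (eng$n_skipatt - eng$n_skipatt_dec)
  if (is.null(duration_model)) {
    t_dec <- n_dec * rep_len(as.numeric(c), n)
    t_com <- n_com * rep_len(as.numeric(c_T), n)
  } else {
    group_sum <- function(counts, sampler) {
      total <- sum(counts)
      if (total == 0L) return(numeric(length(counts)))
      draws <- sampler(total)
      out <- numeric(length(counts))
      got <- rowsum(draws, rep.int(seq_along(counts), counts))
      out[as.integer(rownames(got))] <- got
      out
    }
    t_dec <- group_sum(n_dec, duration_model$r_decided)
    t_com <- group_sum(n_com, duration_model$r_complete)
  }
  list(n_decided = n_dec, n_complete = n_com,
       t_decided = t_dec, t_complete = t_com)
}

chain_records <- function(eng, params, c = params$c, c_T = params$c_T,
                          duration_model = NULL) {
  tm <- chain_times(eng, c, c_T, duration_model)
  n_bs <- eng$n_wrong + eng$n_skipatt_dec
  n_err <- eng$n_wrong + (eng$n_seltask - eng$n_seltask_dec) +
    eng$n_skipatt_dec
  data.frame(
    index = seq_along(eng$kind_sel),
    intended_kind = ifelse(eng$kind_sel, "selection", "skip"),
    delta_t = tm$t_decided + tm$t_complete,
    benefit = ifelse(eng$kind_sel, params$b_sel, params$b_skip),
    n_trials = eng$n_seltask + eng$n_skipatt,
    n_backspaces = n_bs,
    n_system_errors = n_err,
    n_decided_trials = tm$n_decided,
    n_complete_trials = tm$n_complete,
    n_seltask_trials = eng$n_seltask,
    n_seltask_decided = eng$n_seltask_dec,
    n_wrong_selections = eng$n_wrong,
    n_skipatt_trials = eng$n_skipatt,
    n_skipatt_decided = eng$n_skipatt_dec,
    t_decided = tm$t_decided
  )
}

#' Simulation configuration
#'
#' @param params A [full_params()] object.
#' @param k_intentions Number of intended outcomes per process.
#' @param seed Integer seed for the process RNG; recorded in the output.
#' @param max_events_per_intention Guard: a chain exceeding this many trials
#'   raises a divergence error (only expected outside the valid region).
#' @param duration_model `NULL` for deterministic trial durations (`c` per
#'   decided trial, `c_T` per completed trial), or a list with elements
#'   `r_decided` and `r_complete`, each a function of `n` returning `n`
#'   random trial durations in seconds.
#' @return A list of class `bci_sim_config`.
#' @seealso [simulate_process()]
#' @export
sim_config <- function(params, k_intentions = 5000L, seed = 1L,
                       max_events_per_intention = 1e6,
                       duration_model = NULL) {
  stopifnot(inherits(params, "bci_full_params"))
  structure(list(
    params = params,
    k_intentions = chk_count(k_intentions, "k_intentions"),
    seed = chk_count(seed, "seed", min = 0L),
    max_events_per_intention =
      chk_count(max_events_per_intention, "max_events_per_intention"),
    duration_model = duration_model
  ), class = "bci_sim_config")
}

#' Simulate single intention fulfilments
#'
#' One random realization of the event chain that fulfils a backspace, an
#' intended selection, or an intentional skip, under the general scenario.
#' These draw from R's global random number stream; call `set.seed()` first
#' for reproducibility.
#'
#' `simulate_backspace()` returns only the elapsed seconds of the
#' backspace-completion chain (a wrong selection during a backspace leaves
#' two backspaces owed).  The fulfilment functions return a one-row record
#' with the elapsed time `delta_t`, the `benefit` credited, and event counts.
#'
#' @inheritParams sim_config
#' @param max_events Divergence guard, as in [sim_config()].
#' @return `simulate_backspace()`: elapsed seconds.  The fulfilment
#'   functions: a one-row data frame (see [simulate_process()] for the
#'   columns).
#' @export
simulate_backspace <- function(params, max_events = 1e6,
                               duration_model = NULL) {
  stopifnot(inherits(params, "bci_full_params"))
  eng <- sim_chains(TRUE, params$p_sel_given_sel, params$p_correct,
                    params$p_sel_given_skip, max_events)
  tm <- chain_times(eng, params$c, params$c_T, duration_model)
  tm$t_decided + tm$t_complete
}

#' @rdname simulate_backspace
#' @export
simulate_selection_fulfillment <- function(params, max_events = 1e6,
                                           duration_model = NULL) {
  stopifnot(inherits(params, "bci_full_params"))
  eng <- sim_chains(TRUE, params$p_sel_given_sel, params$p_correct,
                    params$p_sel_given_skip, max_events)
  chain_records(eng, params, duration_model = duration_model)
}

#' @rdname simulate_backspace
#' @export
simulate_skip_fulfillment <- function(params, max_events = 1e6,
                                      duration_model = NULL) {
  stopifnot(inherits(params, "bci_full_params"))
  if (params$p_sel_given_skip >= 1)
    divergence_error(max_events)
  eng <- sim_chains(FALSE, params$p_sel_given_sel, params$p_correct,
                    params$p_sel_given_skip, max_events)
  chain_records(eng, params, duration_model = duration_model)
}

#' Simulate a speller usage process
#'
#' Realizes `k_intentions` intended outcomes, each drawn as a selection with
#' probability `pi_sel_i` and otherwise an intentional skip, and fulfils each
#' by the event chains of [simulate_backspace()].  The result records, per
#' intention, the elapsed time, credited benefit, and event counts.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `bci_process`: a list with `records` (one row
#'   per intention), `k_intentions`, `seed`, and `params`.  Record columns
#'   include `intended_kind`, `delta_t` (s), `benefit` (bits), `n_trials`,
#'   `n_backspaces`, `n_system_errors`, and finer event counts used by the
#'   parameter estimators.
#' @seealso [observed_utility()], [write_process()], [as_performance_log()]
#' @export
#' @examples
#' pars <- full_params(0.85, 0.85, 0.85, 0.15, c = 14.75, c_T = 31.625,
#'                     b_sel = log2(36), b_skip = log2(36))
#' pr <- simulate_process(sim_config(pars, k_intentions = 200, seed = 7))
#' observed_utility(pr)
simulate_process <- function(config) {
  stopifnot(inherits(config, "bci_sim_config"))
  set.seed(config$seed)
  p <- config$params
  kind <- stats::runif(config$k_intentions) < p$pi_sel_i
  eng <- sim_chains(kind, p$p_sel_given_sel, p$p_correct,
                    p$p_sel_given_skip, config$max_events_per_intention)
  records <- chain_records(eng, p, duration_model = config$duration_model)
  structure(list(records = records,
                 k_intentions = config$k_intentions,
                 seed = config$seed,
                 params = p),
            class = "bci_process")
}

#' @export
print.bci_process <- function(x, ...) {
  cat(sprintf(
    "Simulated speller process: %d intentions (%d selections, %d skips)\n",
    x$k_intentions, sum(x$records$intended_kind == "selection"),
    sum(x$records$intended_kind == "skip")))
  cat(sprintf("  total time %.1f s, observed average benefit %.5g bit/s\n",
              sum(x$records$delta_t), observed_utility(x)))
  invisible(x)
}

#' Observed average benefit of a process
#'
#' The empirical throughput `UK = sum(benefit) / sum(delta_t)` over the
#' recorded intentions; under the stationary model it converges to the
#' closed-form BCI-Utility as the number of intentions grows.
#'
#' @param process A [simulate_process()] result, or any data frame with
#'   `benefit` and `delta_t` columns.
#' @return Observed average benefit in bit/s.
#' @export
observed_utility <- function(process) {
  records <- if (inherits(process, "bci_process")) process$records
             else process
  if (!is.data.frame(records) ||
      !all(c("benefit", "delta_t") %in% names(records)) ||
      nrow(records) == 0L)
    stop_param("'process' must contain at least one record with 'benefit' ",
               "and 'delta_t'")
  total_t <- sum(records$delta_t)
  if (total_t <= 0) stop_param("total elapsed time must be positive")
  sum(records$benefit) / total_t
}

#' Observed average benefit over many replicated processes
#'
#' Simulates `n_processes` independent speller processes of `k_intentions`
#' intended outcomes each (deterministic trial durations) and returns the
#' observed average benefit of every process.  Processes are simulated in
#' chunks so at most about `chunk` intention chains are held at once.
#'
#' @inheritParams sim_config
#' @param n_processes Number of processes.
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @param max_events Divergence guard per intention.
#' @param chunk Approximate number of intention chains per engine batch
#'   (part of the sampling order, so results are reproducible only for a
#'   fixed value).
#' @return A data frame with columns `process` and `uk` (bit/s).
#' @export
#' @examples
#' pars <- full_params(0.85, 0.85, 0.85, 0.15, c = 14.75, c_T = 31.625,
#'                     b_sel = log2(36), b_skip = log2(36))
#' uk <- simulate_processes(pars, n_processes = 20, k_intentions = 500,
#'                          seed = 1)$uk
#' c(mean(uk), utility_full(pars)$value)
simulate_processes <- function(params, n_processes, k_intentions = 5000L,
                               seed = NULL, max_events = 1e6,
                               chunk = 500000L) {
  stopifnot(inherits(params, "bci_full_params"))
  if (!is.null(seed)) set.seed(seed)
  per_chunk <- max(1L, chunk %/% k_intentions)
  uk <- numeric(n_processes)
  done <- 0L
  while (done < n_processes) {
    m <- min(per_chunk, n_processes - done)
    kind <- stats::runif(m * k_intentions) < params$pi_sel_i
    eng <- sim_chains(kind, params$p_sel_given_sel, params$p_correct,
                      params$p_sel_given_skip, max_events)
    pid <- rep(seq_len(m), each = k_intentions)
    n_dec <- eng$n_seltask_dec + eng$n_skipatt_dec
    n_com <- (eng$n_seltask + eng$n_skipatt) - n_dec
    tt <- rowsum(n_dec * params$c + n_com * params$c_T, pid)
    bb <- rowsum(ifelse(kind, params$b_sel, params$b_skip), pid)
    uk[done + seq_len(m)] <- bb / tt
    done <- done + m
  }
  data.frame(process = seq_len(n_processes), uk = uk)
}

#' Write or read a simulated process
#'
#' The per-intention records are stored as a tab-separated table and the
#' configuration (parameters, number of intentions, seed) as a JSON sidecar
#' named `<path>.json`.
#'
#' @param process A [simulate_process()] result.
#' @param path Path of the tab-separated records file.
#' @return `write_process()` returns `path` invisibly; `read_process()`
#'   returns the reconstructed `bci_process`.
#' @export
write_process <- function(process, path) {
  stopifnot(inherits(process, "bci_process"))
  utils::write.table(process$records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  sidecar <- list(k_intentions = process$k_intentions, seed = process$seed,
                  params = unclass(process$params))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_process
#' @export
read_process <- function(path) {
  records <- utils::read.table(path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  sidecar <- jsonlite::read_json(paste0(path, ".json"),
                                 simplifyVector = TRUE)
  params <- do.call(full_params, sidecar$params[names(formals(full_params))])
  structure(list(records = records,
                 k_intentions = as.integer(sidecar$k_intentions),
                 seed = as.integer(sidecar$seed),
                 params = params),
            class = "bci_process")
}

#' Expand a simulated process into a per-trial performance log
#'
#' Converts the per-intention event counts of a simulated process into one
#' row per trial in the schema consumed by [read_performance_log()] and
#' [session_utility()], which treats each recorded trial as one row.  Trials
#' belonging to error correction (backspaces, retries) are flagged
#' `is_correction = TRUE`; each intention contributes exactly one
#' non-correction row whose `intention` field is the intended kind.
#'
#' Decided trials are assigned `(c - delay) / sequence_duration` sequences
#' and completed trials `sequences_per_complete_trial` sequences, so the
#' duration estimators applied to the log recover `c` and `c_T`.
#'
#' @param process A [simulate_process()] result.
#' @param sequence_duration_ms Duration of one stimulus sequence, ms.
#' @param inter_selection_delay_ms Pause between selections, ms.
#' @param sequences_per_complete_trial Sequences in a complete trial.
#' @param keyboard_size Number of on-screen keys recorded per trial.
#' @return A data frame of per-trial records.
#' @export
as_performance_log <- function(process, sequence_duration_ms,
                               inter_selection_delay_ms,
                               sequences_per_complete_trial,
                               keyboard_size = 37L) {
  stopifnot(inherits(process, "bci_process"))
  r <- process$records
  p <- process$params
  n_seq_dec <- (p$c * 1000 - inter_selection_delay_ms) / sequence_duration_ms
  if (abs(n_seq_dec - round(n_seq_dec)) > 1e-6 || round(n_seq_dec) < 1)
    stop_param("'c' is not representable as a whole number of sequences ",
               "plus the inter-selection delay")
  n_seq_dec <- as.integer(round(n_seq_dec))

  build <- function(counts, made, wrong, intended, first_free) {
    # one block of trials per intention; within an intention, selections
    # (wrong first) precede abstentions
    id <- rep.int(seq_along(counts), counts)
    j <- sequence(counts)
    action_sel <- j <= made[id]
    correct <- rep(NA, length(j))
    if (intended == "selection")
      correct[action_sel] <- j[action_sel] > wrong[id[action_sel]]
    data.frame(
      intention_id = id,
      intention = intended,
      system_action = ifelse(action_sel, "selection", "skip"),
      correct = correct,
      n_sequences = ifelse(action_sel, n_seq_dec,
                           sequences_per_complete_trial),
      is_correction = if (first_free) j != 1L else rep(TRUE, length(j))
    )
  }

  sel <- r$intended_kind == "selection"
  blocks <- list()
  # selection-type task trials of intended selections: wrong selections
  # first, then correct ones, then abstentions; first trial non-correction
  blocks$sel <- build(r$n_seltask_trials[sel], r$n_seltask_decided[sel],
                      r$n_wrong_selections[sel], "selection", TRUE)
  blocks$sel$intention_id <- which(sel)[blocks$sel$intention_id]
  # order within intended selections puts a wrong selection first when one
  # occurred; the non-correction flag marks the first trial regardless
  blocks$skipatt <- build(r$n_skipatt_trials[!sel], r$n_skipatt_decided[!sel],
                          integer(sum(!sel)), "skip", TRUE)
  blocks$skipatt$intention_id <- which(!sel)[blocks$skipatt$intention_id]
  # backspace chains spawned during intended skips: all corrections
  blocks$skipbs <- build(r$n_seltask_trials[!sel], r$n_seltask_decided[!sel],
                         r$n_wrong_selections[!sel], "selection", FALSE)
  blocks$skipbs$intention_id <- which(!sel)[blocks$skipbs$intention_id]

  log <- do.call(rbind, blocks)
  log <- log[order(log$intention_id), , drop = FALSE]
  data.frame(
    intention = log$intention,
    system_action = log$system_action,
    correct = log$correct,
    n_sequences = log$n_sequences,
    sequence_duration_ms = sequence_duration_ms,
    keyboard_size = keyboard_size,
    is_correction = log$is_correction,
    row.names = NULL
  )
}
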