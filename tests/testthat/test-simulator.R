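test_that("perfect accuracies make every fulfilment deterministic", {
  pars <- full_params(0.9, 1, 1, 0, c = 12, c_T = 20, b_sel = 5, b_skip = 4)
  set.seed(1)
  expect_equal(simulate_backspace(pars), 12)
  rec <- simulate_selection_fulfillment(pars)
  expect_equal(rec$delta_t, 12)
  expect_equal(rec$n_trials, 1)
  expect_equal(rec$benefit, 5)
  expect_equal(rec$n_backspaces, 0)
  expect_equal(rec$n_system_errors, 0)
  skp <- simulate_skip_fulfillment(pars)
  expect_equal(skp$delta_t, 20)
  expect_equal(skp$benefit, 4)
  pr <- simulate_process(sim_config(pars, k_intentions = 500, seed = 3))
  sel <- pr$records$intended_kind == "selection"
  expect_true(all(pr$records$delta_t[sel] == 12))
  expect_true(all(pr$records$delta_t[!sel] == 20))
})

test_that("identical seed and config reproduce the process bit for bit", {
  pars <- study_params(0.85, 0.85, 0.85, 0.15)
  cfg <- sim_config(pars, k_intentions = 400, seed = 99)
  p1 <- simulate_process(cfg)
  p2 <- simulate_process(cfg)
  expect_identical(p1$records, p2$records)
  p3 <- simulate_process(sim_config(pars, k_intentions = 400, seed = 100))
  expect_false(identical(p1$records, p3$records))
})

test_that("all intentions are selections when pi_sel_i = 1", {
  pars <- full_params(1, 0.9, 0.9, 0.1, c = 10, c_T = 20,
                      b_sel = 5, b_skip = 5)
  pr <- simulate_process(sim_config(pars, k_intentions = 300, seed = 5))
  expect_true(all(pr$records$intended_kind == "selection"))
})

test_that("simulated fulfilment times agree with the closed forms and the
           recursive oracle", {
  pss <- 0.85; pc <- 0.85; pks <- 0.15
  pars <- study_params(0.5, pss, pc, pks)
  t_sel_cf <- tsel_full(pars)
  t_skip_cf <- tskip_full(pars)
  expect_equal(t_sel_cf, 29.044, tolerance = 1e-4)
  expect_equal(t_skip_cf, 39.353, tolerance = 1e-4)

  set.seed(42)
  pr <- simulate_process(sim_config(pars, k_intentions = 40000, seed = 42))
  sel <- pr$records$intended_kind == "selection"
  dt_sel <- pr$records$delta_t[sel]
  dt_skip <- pr$records$delta_t[!sel]
  expect_lt(abs(mean(dt_sel) - t_sel_cf),
            3 * sd(dt_sel) / sqrt(length(dt_sel)))
  expect_lt(abs(mean(dt_skip) - t_skip_cf),
            3 * sd(dt_skip) / sqrt(length(dt_skip)))

  # the independent recursive oracle agrees with the same closed forms
  set.seed(43)
  orc <- oracle_mean_times(pss, pc, pks, 14.75, 31.625, n = 20000L)
  expect_lt(abs(orc$t_sel - t_sel_cf), 3 * orc$se_sel)
  expect_lt(abs(orc$t_skip - t_skip_cf), 3 * orc$se_skip)
})

test_that("subcritical guard raises a divergence error below 50% accuracy", {
  pars <- full_params(1, 0.85, 0.4, 0.1, c = 10, c_T = 20,
                      b_sel = 5, b_skip = 5)
  # a single chain still completes with probability 2/3 below the critical
  # accuracy; a batch of intentions makes divergence essentially certain
  expect_error(simulate_process(sim_config(pars, k_intentions = 100,
                                           seed = 7,
                                           max_events_per_intention = 2000)),
               class = "bci_divergence_error")
  set.seed(6)
  expect_error(simulate_selection_fulfillment(pars, max_events = 2000),
               class = "bci_divergence_error")
  expect_error(simulate_skip_fulfillment(
    full_params(0, 0.9, 0.9, 1, c = 10, c_T = 20, b_sel = 5, b_skip = 5)),
    class = "bci_divergence_error")
})

test_that("observed utility is total benefit over total time", {
  expect_equal(observed_utility(data.frame(benefit = 5.8, delta_t = 29)),
               0.2)
  rec <- data.frame(benefit = rep(3, 10), delta_t = runif(10, 5, 10))
  expect_equal(observed_utility(rec), 30 / sum(rec$delta_t))
  expect_error(observed_utility(data.frame(benefit = numeric(0),
                                           delta_t = numeric(0))),
               class = "bci_param_error")
})

test_that("event counts are internally consistent", {
  pars <- study_params(0.7, 0.8, 0.8, 0.2)
  pr <- simulate_process(sim_config(pars, k_intentions = 2000, seed = 11))
  r <- pr$records
  expect_true(all(r$n_trials == r$n_decided_trials + r$n_complete_trials))
  expect_true(all(r$n_trials == r$n_seltask_trials + r$n_skipatt_trials))
  expect_true(all(r$n_backspaces ==
                    r$n_wrong_selections + r$n_skipatt_decided))
  # every selection-type task block completes: one completion per intended
  # character plus one per backspace owed
  sel <- r$intended_kind == "selection"
  completions <- r$n_seltask_decided - r$n_wrong_selections
  expect_true(all(completions[sel] == 1 + r$n_backspaces[sel]))
  expect_true(all(completions[!sel] == r$n_backspaces[!sel]))
  expect_true(all(r$delta_t > 0))
})

test_that("a process round-trips through its delimited serialization", {
  pars <- study_params(0.8, 0.9, 0.85, 0.1)
  pr <- simulate_process(sim_config(pars, k_intentions = 150, seed = 21))
  path <- tempfile(fileext = ".tsv")
  write_process(pr, path)
  back <- read_process(path)
  expect_equal(back$records, pr$records)
  expect_equal(back$seed, pr$seed)
  expect_equal(unclass(back$params), unclass(pr$params), tolerance = 1e-12)
  unlink(c(path, paste0(path, ".json")))
})

test_that("stochastic trial durations preserve the mean throughput", {
  dm <- list(r_decided = function(n) runif(n, 10, 19.5),
             r_complete = function(n) rep(31.625, n))
  pars <- study_params(0.85, 0.85, 0.85, 0.15)
  cfg <- sim_config(pars, k_intentions = 20000, seed = 31,
                    duration_model = dm)
  pr <- simulate_process(cfg)
  u <- observed_utility(pr)
  expect_equal(u, utility_full(pars)$value, tolerance = 0.02)
})

test_that("a simulated process expands to a consistent per-trial log", {
  pars <- full_params(0.85, 0.85, 0.85, 0.15, c = 13.75, c_T = 21.25,
                      b_sel = log2(36), b_skip = log2(36))
  pr <- simulate_process(sim_config(pars, k_intentions = 800, seed = 13))
  log <- as_performance_log(pr, sequence_duration_ms = 3750,
                            inter_selection_delay_ms = 10000,
                            sequences_per_complete_trial = 3)
  expect_equal(nrow(log), sum(pr$records$n_trials))
  # one non-correction row per intention, carrying the intended kind
  expect_equal(sum(!log$is_correction), pr$records$index[length(
    pr$records$index)])
  expect_equal(sum(!log$is_correction & log$intention == "selection"),
               sum(pr$records$intended_kind == "selection"))
  # per-trial tallies match the per-intention counts
  expect_equal(sum(log$system_action == "selection"),
               sum(pr$records$n_decided_trials))
  expect_equal(sum(log$correct %in% FALSE),
               sum(pr$records$n_wrong_selections))
  expect_silent(validated <- read_performance_log(
    write_performance_log(log, tempfile(fileext = ".csv"))))
})
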