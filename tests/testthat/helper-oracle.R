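# Independent single-realization oracle for the expected-time chains,
# written as direct recursion on the renewal decompositions (one function
# call per sub-task), deliberately not sharing code with the package's
# pending-counter engine.

# time to complete one selection-type task (a character or a backspace)
oracle_task_time <- function(pss, pc, c, cT) {
  u <- runif(1)
  if (u < pss * pc) return(c)                      # correct selection
  if (u < pss)                                     # wrong selection:
    return(c + oracle_task_time(pss, pc, c, cT) +  # delete it, then
             oracle_task_time(pss, pc, c, cT))     # redo this task
  cT + oracle_task_time(pss, pc, c, cT)            # abstained: retry
}

# time to fulfil an intentional skip
oracle_skip_time <- function(pss, pc, pks, c, cT) {
  if (runif(1) < pks)                              # unintended selection:
    return(c + oracle_task_time(pss, pc, c, cT) +  # delete it, then
             oracle_skip_time(pss, pc, pks, c, cT))  # retry the skip
  cT                                               # correct abstention
}

oracle_mean_times <- function(pss, pc, pks, c, cT, n = 20000L) {
  sel <- replicate(n, oracle_task_time(pss, pc, c, cT))
  skp <- replicate(n, oracle_skip_time(pss, pc, pks, c, cT))
  list(t_sel = mean(sel), se_sel = sd(sel) / sqrt(n),
       t_skip = mean(skp), se_skip = sd(skp) / sqrt(n))
}

# study conditions used throughout the simulation experiments
study_params <- function(pi_sel_i, p_sel_given_sel, p_correct,
                         p_sel_given_skip) {
  full_params(pi_sel_i, p_sel_given_sel, p_correct, p_sel_given_skip,
              c = 14.75, c_T = 31.625, b_sel = log2(36), b_skip = log2(36))
}

session_fixture <- function() {
  read_performance_log(system.file("extdata", "session_synthetic.csv",
                                   package = "bciutility"))
}
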