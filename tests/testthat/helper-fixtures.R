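# Small hand-built cohorts used across tests.

# Three well-formed subjects on a common (0, 1) schedule with C = 2:
# a death mid-window-1, an administrative survivor, a death in window 0.
hand_cohort <- function() {
  sncstm_cohort(list(
    subject_record("a", c(0, 1), c(1, 1), matrix(c(0.5, 0.2), ncol = 1),
                   followup_time = 1.4, event = 1, admin_end = 2),
    subject_record("b", c(0, 1), c(0, 1), matrix(c(-0.3, 0.1), ncol = 1),
                   followup_time = 2, event = 0, admin_end = 2),
    subject_record("c", c(0, 1), c(1, NA), matrix(c(1.1, NA), ncol = 1),
                   followup_time = 0.6, event = 1, admin_end = 2)
  ), covariate_names = "L")
}

# single-visit (point exposure) subject on [0, C]
point_subject <- function(id, A, L, T, event, C = 10) {
  subject_record(id, 0, A, matrix(L, ncol = 1), followup_time = T,
                 event = event, admin_end = C)
}

# quick simulated K = 1 cohort with the default generator settings
quick_sim <- function(n = 600, seed = 100, ...) {
  simulate_cohort(sim_config(n = n, ...), seed = seed)
}
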