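# Shared fixtures, built in code.

# two-arm exponential proportional-hazards data with administrative censoring
sim_two_group <- function(n_per_arm, hr, base_rate = 0.01, censor_at = 60) {
  x <- rep(c(0, 1), each = n_per_arm)
  t_event <- rexp(2 * n_per_arm, base_rate * hr^x)
  data.frame(x = x,
             time = pmin(t_event, censor_at),
             event = as.integer(t_event <= censor_at))
}

# random censored data with optional ties in times and scores
sim_tied <- function(n, max_t = 30, n_scores = 8) {
  data.frame(time = sample(seq_len(max_t), n, replace = TRUE),
             event = rbinom(n, 1, 0.6),
             risk = sample(seq_len(n_scores), n, replace = TRUE))
}

small_training_cohort <- function(n = 400, seed = 11) {
  generate_cohort(training_sim_config(n_patients = n, seed = seed))
}
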