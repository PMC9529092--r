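# small optimizer budget for smoke-level fits; full budgets are used where a
# test is about estimation quality
fast_control <- function(...) {
  fit_control(de_maxiter = 8, polish = FALSE, min_trials = 20, ...)
}

ref_pos <- function() ddm_reference_params("exp1", "positive")
ref_neg <- function() ddm_reference_params("exp1", "negative")

# one-type simulated session at the canonical distances
sim_session <- function(params, per_distance = 72, seed = 1,
                        config = sim_config()) {
  d <- data.frame(log_distance = rep(canonical_pairs()$log_distance,
                                     each = per_distance))
  tr <- simulate_trials(params, d, config, seed = seed)
  tr[tr$choice != "timeout", ]
}
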