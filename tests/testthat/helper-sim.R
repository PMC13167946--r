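# Shared fixtures: small, fast configurations used across test files.

# quiet preprocessing: no motion pass (clean simulations do not need it)
quiet_preproc <- function(...) {
  preproc_config(motion_z = Inf, motion_method = "none", ...)
}

# noise-free, artifact-free simulation config (signal model only)
silent_sim <- function(seed = 1, n_per_group = 2, ...) {
  zero_load <- default_fc_communities()
  zero_load$loadings$loading <- 0
  sim_config(
    seed = seed, n_per_group = n_per_group,
    noise = noise_spec(ar1_sd = 0, white_sd = 0, drift_slope_sd = 0,
                       oscillations = tibble::tibble(
                         freq = numeric(), amp = numeric(),
                         random_phase = logical())),
    artifact = artifact_spec(spike_rate = 0, shift_rate = 0),
    fc = zero_load, amp_subject_sd = 0, resp_sd = 0, ...)
}

# amplitude table with a single constant value everywhere (or zero)
flat_amplitudes <- function(value = 0) {
  a <- default_amplitudes()
  a$amplitude <- value
  a
}

# mean of the task regressor over the task window (closed-form contrast
# factor for a noise-free simulated channel with unit amplitude)
regressor_task_mean <- function(paradigm = vft_paradigm()) {
  reg <- task_regressor(paradigm)
  w <- nirsvft:::paradigm_windows(paradigm)
  mean(reg[w$task]) - mean(reg[w$baseline])
}
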