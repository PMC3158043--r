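# Shared fixtures: small configurations that keep Monte-Carlo test blocks
# fast while exercising the full pipeline. All stimuli are generated in code.

# 1 x 1 deg field, core grid: cheapest full-pipeline config.
tiny_config <- function(...) {
  model_config(field_extent = c(1, 1), ...)
}

# 1 x 2 deg field: the profile used for simulated experiments at 3.8 cpd
# (two grating periods visible; width covers the largest window + offset).
exp_config <- function(...) {
  model_config(field_extent = c(1, 2), ...)
}

# Build a deliberately small bank for decision-stage tests.
small_bank <- function(frequency = 3.8, config = tiny_config(), phases = 4,
                       amplitudes = c(0.3, 2.5), n = 8, seed = 42) {
  build_bank(frequency, config, phases = phases, amplitudes = amplitudes,
             n = n, seed = seed)
}

# Fraction correct over seeded trials for one condition.
pc_of <- function(cond, bank, config, trials, stream, seed = 1L) {
  mean(vapply(seq_len(trials), function(t)
    run_trial(cond, bank, config, seed = derive_seed(seed, stream, t)),
    logical(1)))
}
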