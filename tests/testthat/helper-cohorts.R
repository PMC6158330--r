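# Small cohort specifications used across tests.

noise_free_effects <- function(...) {
  effect_params(baseline_sd_mean_cents = 0, baseline_sd_sd_cents = 0,
                baseline_sd_min_cents = 0, comp_latency_sd_ms = 0,
                following_fraction = 0, eeg_noise_rms_uv = 0,
                artifact_rate = 0, ...)
}

noise_free_spec <- function(n = c(AA = 2, AG = 2, GG = 2), trials = 5, ...) {
  cohort_spec(n_per_genotype = n, trials_per_condition = trials,
              perturbation_onset_range_ms = c(1600, 1600),
              effects = noise_free_effects(...))
}

tiny_spec <- function(n = c(AA = 3, AG = 3, GG = 3), trials = 10, ...) {
  cohort_spec(n_per_genotype = n, trials_per_condition = trials, ...)
}

# A constant-cents epoch builder for vocal unit tests.
make_epoch <- function(values, fs = 100, magnitude = -200, trial_id = 1L) {
  nb <- 20L
  time_ms <- (seq_along(values) - nb - 1L) * 1000 / fs
  structure(list(trial_id = trial_id, time_ms = time_ms, values = values,
                 magnitude_cents = magnitude, baseline_mean_cents = NA_real_,
                 normalized = FALSE, label = NA_character_,
                 reason = NA_character_), class = "vocal_epoch")
}
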