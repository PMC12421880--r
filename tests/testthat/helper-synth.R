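# Shared small-scale fixtures. Tests run sessions at a reduced sampling rate
# and trial count; the generator defaults (full session sizes, 1000 Hz) are
# exercised where the check is about design counts, not signal content.

test_montage <- montage_64()

small_passive <- function(seed = 1, n_per_rate = 10, fs = 250, ...) {
  des <- passive_design(n_per_rate = n_per_rate, seed = seed)
  pars <- neural_sim_params(fs_hz = fs, seed = seed + 100, ...)
  generate_passive_session(des, pars, test_montage, ci_side = "right")
}

# noise-free passive session: deterministic auditory + CI sources only
clean_passive <- function(seed = 1, n_per_rate = 4, fs = 250,
                          ci_artifact_amp = 150) {
  des <- passive_design(n_per_rate = n_per_rate, seed = seed)
  pars <- neural_sim_params(fs_hz = fs, noise_1f_amp = 0, blink_rate_hz = 0,
                            ci_artifact_amp = ci_artifact_amp,
                            seed = seed + 100)
  list(design = des, params = pars,
       session = generate_passive_session(des, pars, test_montage,
                                          ci_side = "right"))
}

small_attention <- function(seed = 1, trials_per_block = 20, fs = 250,
                            ci_side = "right", ...) {
  des <- attention_design(trials_per_block = trials_per_block,
                          cue_front_per_block = trials_per_block / 2,
                          cue_side_per_block = trials_per_block / 2,
                          ci_side = ci_side, seed = seed)
  pars <- neural_sim_params(fs_hz = fs, noise_1f_amp = 1, blink_rate_hz = 0,
                            ci_artifact_amp = 0, seed = seed + 200, ...)
  list(design = des,
       session = generate_attention_session(des, pars, test_montage))
}

# epochs built directly from an array, for unit tests that need exact data
epochs_from_array <- function(arr, fs = 100, t0 = 0,
                              labels = rep("a", dim(arr)[1]),
                              channels = paste0("ch", seq_len(dim(arr)[2]))) {
  eeg_epochs(arr, fs, t0, labels, channels)
}
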