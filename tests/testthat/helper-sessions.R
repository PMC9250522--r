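# small protocols and sessions used across the suite; everything is built
# in code at test time

tiny_protocol <- function(reps_bimodal = 3, reps_unimodal = 5,
                          reps_blank = 6, trial_duration_s = 6, iti_s = 2,
                          frame_rate_hz = 10, stim_onset_s = 3, ...) {
  make_protocol(reps_bimodal = reps_bimodal, reps_unimodal = reps_unimodal,
                reps_blank = reps_blank, trial_duration_s = trial_duration_s,
                iti_s = iti_s, frame_rate_hz = frame_rate_hz,
                stim_onset_s = stim_onset_s, ...)
}

# protocol matching the study's trial counts but imaged coarsely, for
# cheaper statistical simulations (the test statistics only use epoch means)
coarse_protocol <- function(...) {
  make_protocol(trial_duration_s = 8, iti_s = 2, frame_rate_hz = 8,
                stim_onset_s = 3, ...)
}

null_session_epoch_means <- function(protocol, n_cells = 100, seed = 1) {
  sim <- simulate_population(protocol, n_cells = n_cells,
                             frac_odor_mod = 0, odor_identity_amp = 0,
                             seed = seed)
  dff <- compute_dff(neuropil_correct(sim$F, sim$F_n), protocol)
  epoch_average(dff)
}
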