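# Shared fixture builders: everything is generated in code at test time.

quadrants <- c("HAPV", "HANV", "LANV", "LAPV")

# Small montage with named 10-20 electrodes for relevance tests.
small_montage <- c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2")

# A compact EEG spec with a graded planted coupling on (F3, F4): the pair
# shares a 10 Hz oscillator whose amplitude differs per label, so the pair
# features carry label information in every contrast.
coupled_eeg_spec <- function(seed, n_trials = 32, noise_sd = 0.4,
                             amp_mix = 0, coupling_jitter = 0,
                             fs = 64, trial_length = 3) {
  coupling_spec(
    n_channels = length(small_montage), channel_names = small_montage,
    fs_eeg = fs, trial_length = trial_length,
    n_trials_per_subject = n_trials,
    coupled_pairs = data.frame(ch1 = "F3", ch2 = "F4",
                               label = c("HAPV", "HANV", "LANV"),
                               amp = c(1.5, 1, 0.5)),
    coupling_freq = 10, noise_sd = noise_sd, amp_mix = amp_mix,
    coupling_jitter = coupling_jitter, seed = seed
  )
}

# Phase unwrapping for phase-advance checks.
unwrap_phase <- function(phi) {
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(phi[1], d))
}

mean_abs_diff <- function(M) mean(abs(t(apply(as.matrix(M), 1L, diff))))

# Envelope training set from the audio generator (64 samples at 64 Hz).
label_envelope_set <- function(labels, seed) {
  waves <- gen_audio_trials(labels, fs = 8000, seed = seed, trial_length = 1)
  do.call(rbind, lapply(waves, function(w) {
    as.numeric(acoustic_envelope(w, 8000))[1:64]
  }))
}
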