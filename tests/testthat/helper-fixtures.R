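# Shared fixtures: small, fast configurations built in code.

# Clean, noise-free regular rhythm (for exact-timing checks).
clean_config <- function(fs = 1000, duration_s = 30, hr = 60, seed = 3) {
  sim_config(sampling_rate_hz = fs, duration_s = duration_s,
             mean_hr_bpm = hr, hr_sd_bpm = 0,
             snr_db = NULL, white_sd_mv = 0,
             baseline_wander = NULL, powerline = NULL, seed = seed)
}

# Truth beats the detector is allowed to see (i.e. after its learning phase).
visible_truth <- function(truth_idx, fs, learning_s = 2) {
  truth_idx[truth_idx > learning_s * fs]
}

# Independent O(N*L) direct-convolution oracle for the streaming CWT filter.
direct_convolution <- function(x, taps) {
  n <- length(x)
  L <- length(taps)
  y <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(min(i, L))) acc <- acc + taps[j] * x[i - j + 1]
    y[i] <- acc
  }
  y
}
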