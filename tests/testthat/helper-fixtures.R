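# Small in-code fixtures shared across test files.

# A tiny epoch set built directly (not via the simulator): pure Gaussian
# noise plus an optional constant offset added to far trials on one channel
# over a sample window.
make_tiny_epochs <- function(n_per_class = 4, n_channels = 2, n_samples = 6,
                             n_subjects = 2, sfreq = 250, offset = 0,
                             offset_channel = 1, offset_samples = NULL,
                             seed = 1) {
  set.seed(seed)
  n_trials <- 2 * n_per_class * n_subjects
  data <- array(rnorm(n_trials * n_channels * n_samples),
                dim = c(n_trials, n_channels, n_samples))
  labels <- rep(rep(c(1L, -1L), each = n_per_class), n_subjects)
  subjects <- rep(sprintf("S%02d", seq_len(n_subjects)),
                  each = 2 * n_per_class)
  if (offset != 0) {
    offset_samples <- offset_samples %||% seq_len(n_samples)
    data[labels == -1L, offset_channel, offset_samples] <-
      data[labels == -1L, offset_channel, offset_samples] + offset
  }
  times <- (seq_len(n_samples) - 1) / sfreq * 1000
  eeg_epochs(data, times, labels, subjects, sfreq)
}

# A small simulated study: 16 channels, artifact-free by default.
make_small_study <- function(n_subjects = 4, n_trials = 12, n_channels = 16,
                             effects = list(), seed = 1, head = NULL,
                             artifact_rate = 0) {
  head <- head %||% build_toy_headmodel(n_channels, 8, seed = 1)
  cfg <- study_config(n_subjects = n_subjects,
                      n_trials_per_condition = n_trials,
                      n_channels = n_channels, effects = effects,
                      artifact_rate = artifact_rate, seed = seed)
  simulate_study(cfg, head)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
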