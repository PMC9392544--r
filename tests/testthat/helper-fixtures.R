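# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

tiny_profile <- function(effect = 0) {
  subject_profile("S01", "female", 30L, 12L, true_class_effect = effect)
}

tiny_recording <- function(seed = 1, duration = 2, effect = 0,
                           artifacts = artifact_spec(blink_rate = 0,
                                                     line_noise_amp = 0,
                                                     muscle_burst_rate = 0,
                                                     drift_amp = 0),
                           condition = "eyes_closed") {
  generate_recording(tiny_profile(effect),
                     recording_spec(duration = duration,
                                    artifacts = artifacts),
                     seed = seed, condition = condition)
}

# random labelled tensor for augmentation / CV plumbing tests
random_tensor <- function(n = 40, len = 32, ch = 4, seed = 1,
                          n_classes = 2, subjects = 4) {
  set.seed(seed)
  seg <- array(rnorm(n * len * ch), c(n, len, ch))
  labels <- factor(rep(c("a", "b"), length.out = n)[sample(n)],
                   levels = c("a", "b"))
  info <- data.frame(
    subject_id = rep(sprintf("S%02d", seq_len(subjects)), length.out = n),
    session = "pre", condition = "eyes_closed",
    source_offset = 0L, is_artificial = FALSE,
    parent_ids = NA_character_, stringsAsFactors = FALSE)
  segment_tensor(seg, labels, info)
}

# small architecture for training-path tests (keeps tests fast)
tiny_arch <- function(len = 32, ch = 4) {
  architecture_spec(c(len, ch), list(
    layer_conv1d(6, 3), layer_maxpool1d(2),
    layer_conv1d(4, 3), layer_maxpool1d(2),
    layer_lstm(6, return_sequence = TRUE),
    layer_lstm(4, return_sequence = FALSE),
    layer_dense(2)))
}

# one-sided periodogram power in a frequency band (Hz)
band_power <- function(x, fs, low, high) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= low & f <= high
  sum(p[sel])
}
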