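# Shared fixtures: tiny epochs, a tiny encoder spec and a small two-class
# dataset, all generated in code.

sine_epoch <- function(freq = 10, fs = 100, N = 300, C = 1, amp = 1,
                       label = NULL) {
  tt <- (seq_len(N) - 1) / fs
  signal_epoch(matrix(rep(amp * sin(2 * pi * freq * tt), each = C), C, N,
                      byrow = FALSE),
               fs = fs, label = label)
}

random_epoch <- function(C = 4, N = 300, fs = 100, seed = 1) {
  set.seed(seed)
  signal_epoch(matrix(rnorm(C * N), C, N), fs = fs)
}

# tiny encoder: 26 x 8 spectrogram grid, widths 2-3-4-5 (d = 5)
tiny_spec <- function(C = 2, N = 400, fs = 50) {
  encoder_spec(C = C, N = N, fs = fs, stft_window = 50, stft_hop = 50,
               conv_channels = c(2, 3, 4, 5), proj_hidden = 6, proj_dim = 4,
               head_hidden = 6)
}

# small 2-class synthetic set matched to tiny_spec geometry
tiny_dataset <- function(n_subjects = 8, epochs_per_subject = 25, seed = 3) {
  generate_dataset(synthetic_spec(
    K = 2, n_subjects = n_subjects, epochs_per_subject = epochs_per_subject,
    C = 2, N = 400, fs = 50,
    class_bands = list(list(c(3, 1, 1.2)), list(c(12, 1, 1.2))),
    noise_sd = 0.7, subject_effect_sd = 0.1, subject_freq_jitter = 0.1,
    seed = seed))
}

random_unit <- function(m) {
  v <- rnorm(m)
  v / sqrt(sum(v^2))
}

unit_rows <- function(M, m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(rnorm(M * m), M, m)
  Z / sqrt(rowSums(Z^2))
}
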