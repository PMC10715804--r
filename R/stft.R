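# Short-time Fourier transform front end of the encoder.

stft_frame_count <- function(N, window, hop) {
  if (window > N)
    stopf("STFT window (%d samples) is longer than the epoch (%d samples)",
          window, N)
  (N - window) %/% hop + 1L
}

stft_window_values <- function(window_fn, L) {
  switch(window_fn,
         hann = 0.5 * (1 - cos(2 * pi * (0:(L - 1L)) / L)),
         rect = rep(1, L),
         stopf("unknown STFT window function '%s'", window_fn))
}

# batched STFT over signals in column layout (X: N x (n*C), sample-major
# columns with channels in order) -> magnitude array (F, Tframes, C, n),
# the layout the convolutional stack consumes
stft_cols <- function(X, n, C, window, hop, window_fn = "hann",
                      log_compress = TRUE) {
  N <- nrow(X)
  Tf <- stft_frame_count(N, window, hop)
  nF <- window %/% 2L + 1L
  win <- stft_window_values(window_fn, window)
  starts <- seq(1L, by = hop, length.out = Tf)
  idx <- outer(0:(window - 1L), starts, "+")   # window x Tf
  frames <- X[as.vector(idx), , drop = FALSE]  # (window*Tf) x (n*C)
  dim(frames) <- c(window, Tf * n * C)
  frames <- frames * win
  sp <- Mod(mvfft(frames))[seq_len(nF), , drop = FALSE]
  # column order is (frame, channel, sample), so this is (F, T, C, n)
  dim(sp) <- c(nF, Tf, C, n)
  if (log_compress) sp <- log1p(sp)
  sp
}

signals_to_cols <- function(signals) {
  d <- dim(signals)
  matrix(aperm(signals, c(3L, 2L, 1L)), nrow = d[3L])
}

# batched STFT: signals (n, C, N) -> (F, Tframes, C, n)
stft_batch <- function(signals, window, hop, window_fn = "hann",
                       log_compress = TRUE) {
  d <- dim(signals)
  stft_cols(signals_to_cols(signals), d[1L], d[2L], window, hop,
            window_fn, log_compress)
}

#' Compute the magnitude spectrogram of an epoch
#'
#' Slides a window of `spec$stft_window` samples with hop
#' `spec$stft_hop` along each channel, multiplies by the window function
#' and takes the magnitude of the discrete Fourier transform, keeping the
#' `window/2 + 1` non-redundant frequency bins.  Frame t covers samples
#' `(t-1)*hop + 1 .. (t-1)*hop + window`; the number of frames is
#' `floor((N - window)/hop) + 1` and any trailing partial frame is
#' dropped.  Optionally `log(1 + .)` compressed.
#'
#' @param x a [signal_epoch()].
#' @param spec an [encoder_spec()] carrying the STFT parameters.
#' @return A numeric array of dimension `c(C, F, Tframes)` with
#'   `F = stft_window/2 + 1`.
#' @examples
#' sp <- encoder_spec(C = 1, N = 300, fs = 100, stft_window = 100,
#'                    stft_hop = 50, conv_channels = c(2, 2, 2, 2))
#' x <- signal_epoch(matrix(sin(2 * pi * 10 * (0:299) / 100), 1), fs = 100)
#' s <- stft_spectrogram(x, sp)
#' dim(s)  # 1 channel x 51 bins x 5 frames
#' @export
stft_spectrogram <- function(x, spec) {
  stopifnot(inherits(x, "signal_epoch"), inherits(spec, "encoder_spec"))
  C <- nrow(x$data); N <- ncol(x$data)
  sig <- array(x$data, dim = c(1L, C, N))
  sp <- stft_batch(sig, spec$stft_window, spec$stft_hop,
                   spec$stft_window_fn, spec$log_compress)
  arr <- sp[, , , 1L, drop = FALSE]
  dim(arr) <- dim(sp)[1:3]
  aperm(arr, c(3L, 1L, 2L))
}
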