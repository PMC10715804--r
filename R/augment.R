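# Signal augmentations: bandpass filtering, band-limited noising, channel
# flipping and circular time shifting, plus the two-view sampling policy
# used during pretraining.  All stochastic ops are pure functions of
# (input, parameters, seed).

#' Define an augmentation policy
#'
#' Controls which augmentations are applied when producing the two views
#' of an epoch, and their parameter ranges.  Per view, a uniformly random
#' non-empty subset of the enabled operations is drawn, except that
#' channel flipping is never applied on its own (a flip of symmetric
#' channels alone produces a view statistically indistinguishable from
#' the original, so it must be combined with another perturbation).
#' When all four operations are enabled this subsetting applies flipping
#' with probability exactly 1/2 per view.
#'
#' @param enabled_ops character subset of
#'   `c("bandpass", "noising", "flipping", "shifting")`.
#' @param bandpass_low,bandpass_high band edges in Hz for the bandpass
#'   augmentation; must satisfy `0 < low < high < fs/2` at application
#'   time.  The default 0.5--30 Hz covers the standard sleep-EEG band.
#' @param noise_snr_db signal-to-noise ratio in dB for the noising
#'   augmentation; either a single value or a length-2 range from which a
#'   value is drawn uniformly per view (default 5--20 dB: mild,
#'   label-preserving perturbations).
#' @param flip_pairs list of length-2 integer vectors naming channel
#'   pairs to swap (left/right sensor symmetry), or `NULL` to pair
#'   consecutive channels `(1,2), (3,4), ...` at application time.
#' @param max_shift maximum circular shift in samples (drawn uniformly in
#'   `-max_shift..max_shift` per view), or `NULL` for `fs/2` samples
#'   (half a second), small relative to a 30-s epoch.
#' @return An object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(enabled_ops = c("bandpass", "noising",
                                                "flipping", "shifting"),
                                bandpass_low = 0.5, bandpass_high = 30,
                                noise_snr_db = c(5, 20),
                                flip_pairs = NULL, max_shift = NULL) {
  all_ops <- c("bandpass", "noising", "flipping", "shifting")
  enabled_ops <- unique(as.character(enabled_ops))
  bad <- setdiff(enabled_ops, all_ops)
  if (length(bad))
    stopf("unknown augmentation op(s): %s", paste(bad, collapse = ", "))
  if (identical(enabled_ops, "flipping"))
    stopf("channel flipping cannot be the only enabled augmentation")
  if (!is_number(bandpass_low) || !is_number(bandpass_high) ||
      bandpass_low <= 0 || bandpass_high <= bandpass_low)
    stopf("invalid bandpass edges: low = %s, high = %s (need 0 < low < high)",
          format(bandpass_low), format(bandpass_high))
  if (!is.numeric(noise_snr_db) || !length(noise_snr_db) %in% 1:2 ||
      any(!is.finite(noise_snr_db)))
    stopf("'noise_snr_db' must be a finite value or range")
  if (length(noise_snr_db) == 2L && noise_snr_db[2L] < noise_snr_db[1L])
    stopf("'noise_snr_db' range must be increasing")
  if (!is.null(flip_pairs)) validate_flip_pairs(flip_pairs, C = NULL)
  if (!is.null(max_shift) && (!is_count(max_shift, min = 0L)))
    stopf("'max_shift' must be a non-negative integer number of samples")
  structure(list(enabled_ops = enabled_ops, bandpass_low = bandpass_low,
                 bandpass_high = bandpass_high, noise_snr_db = noise_snr_db,
                 flip_pairs = flip_pairs, max_shift = max_shift),
            class = "augmentation_policy")
}

validate_flip_pairs <- function(pairs, C) {
  if (!is.list(pairs))
    stopf("'flip_pairs' must be a list of channel index pairs")
  idx <- integer(0)
  for (p in pairs) {
    if (length(p) != 2L || any(p != round(p)) || any(p < 1L) || p[1L] == p[2L])
      stopf("invalid flip pair (%s)", paste(p, collapse = ", "))
    idx <- c(idx, as.integer(p))
  }
  if (anyDuplicated(idx))
    stopf("flip pairs overlap: channel %d appears twice", idx[duplicated(idx)][1L])
  if (!is.null(C) && length(idx) && max(idx) > C)
    stopf("flip pair channel %d exceeds channel count %d", max(idx), C)
  invisible(pairs)
}

default_flip_pairs <- function(C) {
  if (C < 2L) return(list())
  lapply(seq_len(C %/% 2L), function(p) c(2L * p - 1L, 2L * p))
}

# squared magnitude response of an analog order-1 Butterworth bandpass,
# H(s) = B s / (s^2 + B s + w0^2) with B = high - low, w0^2 = low * high;
# zero-phase (forward-backward) filtering applies this |H|^2 as the gain
butter1_bp_gain <- function(f, low, high) {
  w2 <- f^2
  B <- high - low
  w02 <- low * high
  B^2 * w2 / ((w02 - w2)^2 + B^2 * w2)
}

# circular zero-phase bandpass of a C x N matrix via the FFT
bandpass_mat <- function(x, fs, low, high) {
  N <- ncol(x)
  k <- 0:(N - 1L)
  f <- pmin(k, N - k) * fs / N  # two-sided bin frequencies
  gain <- butter1_bp_gain(f, low, high)
  X <- mvfft(t(x))
  t(Re(mvfft(X * gain, inverse = TRUE)) / N)
}

#' Bandpass-filter an epoch (order-1 Butterworth, zero phase)
#'
#' Attenuates frequency content outside `[low, high]` Hz.  The filter is
#' applied in the frequency domain as the squared magnitude response of an
#' order-1 Butterworth bandpass (the zero-phase forward-backward
#' equivalent), circularly, so the output is not time-shifted and the
#' operation commutes with [time_shift()].
#'
#' @param x a [signal_epoch()].
#' @param low,high band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @return A filtered `signal_epoch` of the same shape.
#' @examples
#' x <- signal_epoch(matrix(sin(2 * pi * 10 * (0:299) / 100), 1), fs = 100)
#' y <- bandpass_filter(x, 1, 30)   # 10 Hz passes nearly unattenuated
#' @export
bandpass_filter <- function(x, low, high) {
  stopifnot(inherits(x, "signal_epoch"))
  if (!is_number(low) || !is_number(high) ||
      low <= 0 || high <= low || high >= x$fs / 2)
    stopf("invalid band edges low = %s, high = %s for fs = %g (need 0 < low < high < fs/2)",
          format(low), format(high), x$fs)
  signal_epoch(bandpass_mat(x$data, x$fs, low, high), x$fs, x$label)
}

# band-limited white noise scaled to a per-channel SNR; draws from the
# ambient RNG stream
noise_mat <- function(x, fs, snr_db, band) {
  C <- nrow(x); N <- ncol(x)
  p_sig <- rowMeans(x^2)
  if (any(p_sig == 0))
    stopf("signal-to-noise ratio undefined: channel %d has zero power",
          which(p_sig == 0)[1L])
  noise <- matrix(rnorm(C * N), C, N)
  # brickwall the noise into the requested band
  k <- 0:(N - 1L)
  f <- pmin(k, N - k) * fs / N
  keep <- f >= band[1L] & f <= band[2L]
  if (!any(keep)) keep[which.min(abs(f - mean(band)))] <- TRUE
  Xn <- mvfft(t(noise))
  Xn[!keep, ] <- 0
  noise <- t(Re(mvfft(Xn, inverse = TRUE)) / N)
  p_noise <- rowMeans(noise^2)
  scale <- sqrt(p_sig / (pmax(p_noise, .Machine$double.xmin) *
                           10^(snr_db / 10)))
  x + noise * scale
}

#' Add band-limited noise at a target signal-to-noise ratio
#'
#' Adds white noise confined to a frequency band, scaled per channel so
#' that the power ratio of signal to noise equals `snr_db` decibels,
#' mimicking low- or high-frequency physical distortion of the sensors.
#'
#' @param x a [signal_epoch()]; must have nonzero power on every channel.
#' @param snr_db target signal-to-noise ratio in dB.
#' @param band length-2 numeric band `c(low, high)` in Hz, or `NULL` to
#'   pick randomly (part of the seeded draw) between a low band 0--2 Hz
#'   and a high band fs/4--fs/2.
#' @param seed integer seed fixing the noise realization.
#' @return A `signal_epoch` equal to `x` plus the scaled noise.
#' @export
add_noise <- function(x, snr_db, band = NULL, seed) {
  stopifnot(inherits(x, "signal_epoch"))
  if (!is_number(snr_db)) stopf("'snr_db' must be a finite number")
  if (!is.null(band)) {
    if (!is.numeric(band) || length(band) != 2L || band[2L] <= band[1L] ||
        band[1L] < 0)
      stopf("'band' must be c(low, high) with 0 <= low < high")
  }
  with_seed(seed, {
    if (is.null(band)) {
      band <- if (runif(1) < 0.5) c(0, 2) else c(x$fs / 4, x$fs / 2)
    }
    signal_epoch(noise_mat(x$data, x$fs, snr_db, band), x$fs, x$label)
  })
}

flip_mat <- function(x, pairs) {
  for (p in pairs) {
    tmp <- x[p[1L], ]
    x[p[1L], ] <- x[p[2L], ]
    x[p[2L], ] <- tmp
  }
  x
}

#' Swap symmetric channel pairs
#'
#' Exchanges the rows of each listed channel pair, modelling the
#' left/right symmetry of sensors placed on opposite sides of the head.
#' Applying the same flip twice restores the original epoch.
#'
#' @param x a [signal_epoch()].
#' @param pairs list of length-2 integer vectors of channel indices;
#'   pairs must be disjoint and within range.
#' @return A `signal_epoch` with the paired rows exchanged.
#' @export
channel_flip <- function(x, pairs) {
  stopifnot(inherits(x, "signal_epoch"))
  validate_flip_pairs(pairs, C = nrow(x$data))
  signal_epoch(flip_mat(x$data, pairs), x$fs, x$label)
}

shift_mat <- function(x, shift) {
  N <- ncol(x)
  idx <- ((seq_len(N) - 1L - shift) %% N) + 1L
  x[, idx, drop = FALSE]
}

#' Circularly shift an epoch in time
#'
#' Advances (negative shift) or delays (positive shift) every channel by
#' a whole number of samples, wrapping circularly so per-channel energy
#' and spectrum are preserved exactly and no edge padding is needed.
#'
#' @param x a [signal_epoch()].
#' @param shift integer number of samples, `|shift| < N`; positive
#'   delays the signal.
#' @return The shifted `signal_epoch`.
#' @export
time_shift <- function(x, shift) {
  stopifnot(inherits(x, "signal_epoch"))
  N <- ncol(x$data)
  if (!is_number(shift) || shift != round(shift))
    stopf("'shift' must be an integer number of samples")
  if (abs(shift) >= N)
    stopf("|shift| = %d must be smaller than the epoch length N = %d",
          abs(shift), N)
  signal_epoch(shift_mat(x$data, as.integer(shift)), x$fs, x$label)
}

# enumerate the valid op subsets for one view: non-empty subsets of the
# enabled ops, excluding {flipping} alone
valid_op_subsets <- function(enabled) {
  n <- length(enabled)
  if (n == 0L) return(list(character(0)))
  subsets <- list()
  for (mask in seq_len(2^n - 1L)) {
    s <- enabled[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
    if (identical(s, "flipping")) next
    subsets[[length(subsets) + 1L]] <- s
  }
  if (!length(subsets)) list(character(0)) else subsets
}

# apply one randomly parameterized view to a C x N matrix, drawing from
# the ambient RNG stream; ops applied in the fixed order
# bandpass -> noising -> flipping -> shifting
augment_view_mat <- function(x, fs, policy) {
  t(augment_views_cols(t(x), n = 1L, C = nrow(x), fs = fs, policy = policy))
}

# Band-limited Gaussian noise synthesized directly in the frequency
# domain (equivalent in distribution to brickwall-filtered white noise):
# one N x k matrix of realizations confined to [band[1], band[2]] Hz.
bandlimited_noise_cols <- function(N, k, fs, band) {
  kk <- 0:(N - 1L)
  f <- pmin(kk, N - kk) * fs / N
  half <- which(f >= band[1L] & f <= band[2L] & kk <= N / 2)
  if (!length(half)) half <- which.min(abs(f - mean(band)))
  Z <- matrix(0 + 0i, N, k)
  Z[half, ] <- matrix(rnorm(length(half) * k) + 1i * rnorm(length(half) * k),
                      length(half), k)
  # Hermitian symmetry so the inverse transform is real
  pos <- half[half > 1L & (half - 1L) < N / 2]
  Z[N - pos + 2L, ] <- Conj(Z[pos, , drop = FALSE])
  Z[1L, ] <- Re(Z[1L, ])
  if (N %% 2L == 0L) Z[N / 2L + 1L, ] <- Re(Z[N / 2L + 1L, ])
  Re(mvfft(Z, inverse = TRUE)) / N
}

# One augmented view of a batch held in column layout: X is N x (n*C)
# with sample i occupying columns (i-1)*C + 1 .. i*C (channels in order).
# Each sample draws its own op subset and parameters from the ambient RNG
# stream; the ops run vectorized over the samples that drew them.  All
# random parameters are drawn up front in a fixed order, so the draw
# sequence does not depend on the signal values.
augment_views_cols <- function(X, n, C, fs, policy) {
  N <- nrow(X)
  subsets <- valid_op_subsets(policy$enabled_ops)
  pick <- sample.int(length(subsets), n, replace = TRUE)
  has_op <- function(op) vapply(pick, function(p) op %in% subsets[[p]], TRUE)
  snr <- if (length(policy$noise_snr_db) == 2L)
    runif(n, policy$noise_snr_db[1L], policy$noise_snr_db[2L])
  else rep(policy$noise_snr_db, n)
  low_band <- runif(n) < 0.5
  ms <- if (is.null(policy$max_shift)) max(1L, round(fs / 2))
        else policy$max_shift
  ms <- min(ms, N - 1L)
  shifts <- sample.int(2L * ms + 1L, n, replace = TRUE) - ms - 1L
  sample_cols <- function(sel) as.vector(outer(seq_len(C), (sel - 1L) * C, "+"))

  sel <- which(has_op("bandpass"))
  if (length(sel)) {
    kk <- 0:(N - 1L)
    f <- pmin(kk, N - kk) * fs / N
    gain <- butter1_bp_gain(f, policy$bandpass_low,
                            min(policy$bandpass_high, fs / 2 * 0.999))
    cols <- sample_cols(sel)
    Xf <- mvfft(X[, cols, drop = FALSE])
    X[, cols] <- Re(mvfft(Xf * gain, inverse = TRUE)) / N
  }
  sel <- which(has_op("noising"))
  if (length(sel)) {
    cols <- sample_cols(sel)
    sub <- X[, cols, drop = FALSE]
    p_sig <- colMeans(sub^2)
    if (any(p_sig == 0))
      stopf("signal-to-noise ratio undefined: a channel has zero power")
    noise <- matrix(0, N, length(cols))
    for (lowband in c(TRUE, FALSE)) {
      grp <- which(low_band[sel] == lowband)
      if (!length(grp)) next
      band <- if (lowband) c(0, 2) else c(fs / 4, fs / 2)
      gcols <- as.vector(outer(seq_len(C), (grp - 1L) * C, "+"))
      noise[, gcols] <- bandlimited_noise_cols(N, length(gcols), fs, band)
    }
    p_noise <- pmax(colMeans(noise^2), .Machine$double.xmin)
    scale <- sqrt(p_sig / (p_noise * 10^(rep(snr[sel], each = C) / 10)))
    X[, cols] <- sub + noise * rep(scale, each = N)
  }
  sel <- which(has_op("flipping"))
  if (length(sel)) {
    pairs <- if (is.null(policy$flip_pairs)) default_flip_pairs(C)
             else policy$flip_pairs
    validate_flip_pairs(pairs, C)
    perm <- seq_len(C)
    for (p in pairs) perm[p] <- rev(perm[p])
    cols <- sample_cols(sel)
    permuted <- as.vector(outer(perm, (sel - 1L) * C, "+"))
    X[, cols] <- X[, permuted, drop = FALSE]
  }
  sel <- which(has_op("shifting"))
  for (i in sel) {
    s <- shifts[i]
    if (s != 0L) {
      idx <- ((seq_len(N) - 1L - s) %% N) + 1L
      cols <- ((i - 1L) * C + 1L):(i * C)
      X[, cols] <- X[idx, cols, drop = FALSE]
    }
  }
  X
}

#' Produce two independently augmented views of an epoch
#'
#' Draws, for each of the two views, a uniformly random non-empty subset
#' of the policy's enabled operations (never flipping alone) with
#' independently drawn parameters, and applies them in a fixed order
#' (bandpass, noising, flipping, shifting).  The pair of views forms the
#' positive pair of the contrastive objective.
#'
#' @param x a [signal_epoch()].
#' @param policy an [augmentation_policy()].
#' @param seed integer seed; the same `(x, policy, seed)` always yields
#'   the identical pair of views.
#' @return A list of two `signal_epoch` views.
#' @export
make_views <- function(x, policy, seed) {
  stopifnot(inherits(x, "signal_epoch"), inherits(policy, "augmentation_policy"))
  with_seed(seed, {
    v1 <- augment_view_mat(x$data, x$fs, policy)
    v2 <- augment_view_mat(x$data, x$fs, policy)
    list(signal_epoch(v1, x$fs, x$label), signal_epoch(v2, x$fs, x$label))
  })
}
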