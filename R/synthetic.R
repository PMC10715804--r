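# Synthetic multichannel signal generator with sleep-stage-like spectral
# class structure, so every module is testable without external data.

#' Default class spectral templates
#'
#' Five classes whose oscillatory bands echo the canonical AASM stage
#' signatures: W (alpha, 10 Hz), N1 (low-amplitude theta, 6 Hz), N2
#' (sigma-band spindles, 13 Hz), N3 (high-amplitude delta, 1.5 Hz) and R
#' (mixed 5 + 20 Hz).  Each entry is a list of `c(center_hz,
#' bandwidth_hz, amplitude)` triplets; the templates are configuration,
#' not a claim of physiological fidelity.
#'
#' @return A named list of band lists.
#' @export
default_class_bands <- function() {
  list(W  = list(c(10,  2,   1.0)),
       N1 = list(c(6,   2,   0.6)),
       N2 = list(c(13,  2,   0.9)),
       N3 = list(c(1.5, 1,   1.5)),
       R  = list(c(5,   2,   0.7), c(20, 4, 0.5)))
}

#' Specify a synthetic dataset
#'
#' Describes a labeled multichannel dataset in which classes differ by
#' spectral content: each epoch of class k is a sum of band-limited
#' oscillations at class k's bands plus white noise, scaled by a
#' per-subject random gain.  Channels come in mirror pairs that share the
#' oscillatory component (with independent noise), so channel flipping is
#' label-preserving, as the left/right sensor symmetry argument assumes.
#'
#' @param K number of classes (must match `length(class_bands)`).
#' @param n_subjects number of subjects.
#' @param epochs_per_subject epochs per subject; labels cycle through the
#'   K classes, so counts are balanced whenever K divides the total.
#' @param C channel count (even, so mirror pairs exist).
#' @param N samples per epoch.
#' @param fs sampling rate in Hz.
#' @param class_bands per-class list of `c(center, bandwidth, amplitude)`
#'   triplets; centers must lie below fs/2.  `NULL` uses
#'   [default_class_bands()] when `K = 5`, otherwise K single bands
#'   spread evenly across the spectrum.
#' @param noise_sd standard deviation of the additive white noise.
#' @param subject_effect_sd log-scale SD of the per-subject gain
#'   (`gain = exp(rnorm(1, 0, subject_effect_sd))`).
#' @param subject_freq_jitter SD in Hz of a per-subject shift of all band
#'   centers, giving epochs of one subject a shared spectral fingerprint.
#' @param seed integer seed; the dataset is a pure function of the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(K = 5L, n_subjects = 40L, epochs_per_subject = 50L,
                           C = 4L, N = 3000L, fs = 100,
                           class_bands = NULL,
                           noise_sd = 1.5, subject_effect_sd = 0.2,
                           subject_freq_jitter = 0.25, seed = 1L) {
  if (!is_count(K, min = 2L)) stopf("'K' must be an integer >= 2")
  if (is.null(class_bands)) {
    class_bands <- if (K == 5L) default_class_bands()
    else lapply(seq(0.1 * fs / 2, 0.7 * fs / 2, length.out = K),
                function(ctr) list(c(ctr, max(1, 0.04 * fs), 1)))
  }
  if (length(class_bands) != K)
    stopf("'class_bands' must have one entry per class (%d), got %d",
          K, length(class_bands))
  if (!is_count(C, min = 2L) || C %% 2L != 0L)
    stopf("'C' must be an even channel count so mirror pairs exist")
  if (!is_count(N, min = 8L)) stopf("'N' must be an integer >= 8")
  if (!is_number(fs) || fs <= 0) stopf("'fs' must be positive")
  for (k in seq_len(K)) {
    for (band in class_bands[[k]]) {
      if (length(band) != 3L || band[1L] <= 0 || band[1L] >= fs / 2)
        stopf("class %d: band center %g must lie in (0, fs/2)", k, band[1L])
      if (band[2L] < 0 || band[3L] <= 0)
        stopf("class %d: bandwidth must be >= 0 and amplitude > 0", k)
    }
  }
  if (!is_number(noise_sd) || noise_sd < 0) stopf("'noise_sd' must be >= 0")
  if (!is_number(subject_effect_sd) || subject_effect_sd < 0)
    stopf("'subject_effect_sd' must be >= 0")
  if (!is_number(subject_freq_jitter) || subject_freq_jitter < 0)
    stopf("'subject_freq_jitter' must be >= 0")
  if (!is_count(n_subjects)) stopf("'n_subjects' must be a positive integer")
  if (!is_count(epochs_per_subject))
    stopf("'epochs_per_subject' must be a positive integer")
  structure(list(K = as.integer(K), n_subjects = as.integer(n_subjects),
                 epochs_per_subject = as.integer(epochs_per_subject),
                 C = as.integer(C), N = as.integer(N), fs = as.numeric(fs),
                 class_bands = class_bands, noise_sd = noise_sd,
                 subject_effect_sd = subject_effect_sd,
                 subject_freq_jitter = subject_freq_jitter,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# band-limited realization drawn from the ambient RNG stream
bandlimited_mat <- function(center, bw, amp, N, fs) {
  if (amp == 0) return(numeric(N))
  x <- rnorm(N)
  k <- 0:(N - 1L)
  f <- pmin(k, N - k) * fs / N
  lo <- max(center - bw / 2, fs / N)
  hi <- min(center + bw / 2, fs / 2)
  keep <- f >= lo & f <= hi & f > 0
  if (!any(keep)) keep[which.min(abs(f - center) + (f == 0) * fs)] <- TRUE
  X <- fft(x)
  X[!keep] <- 0
  y <- Re(fft(X, inverse = TRUE)) / N
  r <- sqrt(mean(y^2))
  if (r == 0) return(numeric(N))
  y * (amp / r)
}

#' Generate a band-limited oscillation
#'
#' White noise filtered to the band `[center - bw/2, center + bw/2]` and
#' rescaled so its RMS amplitude equals `amp` exactly.  As `bw` shrinks
#' to a single frequency bin the signal approaches a pure sinusoid at
#' `center`.
#'
#' @param center center frequency in Hz, `0 < center < fs/2`.
#' @param bw bandwidth in Hz (>= 0).
#' @param amp target RMS amplitude.
#' @param N number of samples.
#' @param fs sampling rate in Hz.
#' @param seed integer seed fixing the realization.
#' @return A numeric vector of length N.
#' @export
bandlimited_oscillation <- function(center, bw, amp, N, fs, seed = 1L) {
  if (!is_number(center) || center <= 0 || center >= fs / 2)
    stopf("'center' must lie in (0, fs/2), got %s", format(center))
  if (!is_number(bw) || bw < 0) stopf("'bw' must be >= 0")
  if (!is_number(amp) || amp < 0) stopf("'amp' must be >= 0")
  with_seed(seed, bandlimited_mat(center, bw, amp, N, fs))
}

#' Generate a labeled synthetic dataset
#'
#' Realizes the dataset described by a [synthetic_spec()]: for every
#' subject, a random gain and a small spectral shift are drawn once, and
#' each epoch sums that subject's class-band oscillations (shared within
#' each mirror channel pair) with independent white noise per channel.
#' Labels cycle deterministically through the classes, so the label
#' sequence is identical across seeds while the signal realizations
#' differ.
#'
#' @param spec a [synthetic_spec()].
#' @return A labeled [epoch_dataset()] with subjects `S001, S002, ...`
#'   and channel names `p1L, p1R, p2L, p2R, ...`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_subjects * spec$epochs_per_subject
  signals <- array(0, dim = c(n, spec$C, spec$N))
  labels <- integer(n)
  subject <- character(n)
  npairs <- spec$C %/% 2L
  with_seed(spec$seed, {
    i <- 0L
    for (s in seq_len(spec$n_subjects)) {
      sid <- sprintf("S%03d", s)
      gain <- exp(rnorm(1L, 0, spec$subject_effect_sd))
      jitter <- rnorm(1L, 0, spec$subject_freq_jitter)
      lab_seq <- rep_len(0:(spec$K - 1L), spec$epochs_per_subject)
      for (e in seq_len(spec$epochs_per_subject)) {
        i <- i + 1L
        k <- lab_seq[e]
        labels[i] <- k
        subject[i] <- sid
        for (p in seq_len(npairs)) {
          osc <- numeric(spec$N)
          for (band in spec$class_bands[[k + 1L]]) {
            ctr <- min(max(band[1L] + jitter, spec$fs / spec$N),
                       spec$fs / 2 - spec$fs / spec$N)
            osc <- osc + bandlimited_mat(ctr, band[2L], band[3L],
                                         spec$N, spec$fs)
          }
          osc <- gain * osc
          for (ch in c(2L * p - 1L, 2L * p)) {
            noise <- if (spec$noise_sd > 0)
              rnorm(spec$N, 0, spec$noise_sd) else 0
            signals[i, ch, ] <- osc + noise
          }
        }
      }
    }
  })
  cn <- as.vector(t(outer(seq_len(npairs), c("L", "R"),
                          function(p, s) sprintf("p%d%s", p, s))))
  epoch_dataset(signals, spec$fs, subject, labels = labels,
                channel_names = cn)
}
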