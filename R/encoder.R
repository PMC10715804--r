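# STFT-CNN encoder f(.) and unit-hypersphere projector g(.).

#' Describe the encoder and projector architecture
#'
#' The encoder maps an epoch to a d-dimensional representation by
#' cascading an STFT spectrogram, one 3x3 convolution (stride 1) and
#' three convolutional blocks of (3x3 convolution, ELU, 2x2 max-pool),
#' followed by a global average pool, so `d` equals the last
#' convolutional width.  The projector is a 2-layer perceptron
#' `d -> proj_hidden -> proj_dim` with an ELU in between, whose output is
#' L2-normalized onto the unit hypersphere where the contrastive loss
#' lives.
#'
#' @param C,N,fs channel count, samples per epoch and sampling rate of
#'   the epochs the encoder will consume.
#' @param stft_window STFT window length in samples (default `2*fs`, a
#'   2-second window giving 0.5 Hz resolution).
#' @param stft_hop STFT hop in samples (default `fs/2`).
#' @param stft_window_fn `"hann"` (default) or `"rect"`.
#' @param log_compress apply `log(1 + .)` to the magnitude spectrogram
#'   (default `TRUE`).
#' @param normalize_input standardize each spectrogram (zero mean, unit
#'   variance over all channels and pixels) before the convolutional
#'   stack (default `TRUE`).
#' @param conv_channels integer vector of 4 widths: the stem convolution
#'   and the three blocks; the representation size is
#'   `d = conv_channels[4]`.
#' @param proj_hidden hidden width of the projector.
#' @param proj_dim m, the projection dimension.
#' @param head_hidden hidden width of the 2-layer classification head of
#'   the supervised reference model.
#' @return An object of class `encoder_spec`, with derived fields
#'   `n_freq`, `n_frames` (spectrogram grid), `repr_dim` (d).
#' @seealso [init_encoder()], [encode()], [project()]
#' @export
encoder_spec <- function(C, N, fs, stft_window = 2 * fs, stft_hop = fs / 2,
                         stft_window_fn = c("hann", "rect"),
                         log_compress = TRUE, normalize_input = TRUE,
                         conv_channels = c(8L, 16L, 32L, 64L),
                         proj_hidden = 64L, proj_dim = 32L,
                         head_hidden = 128L) {
  stft_window_fn <- match.arg(stft_window_fn)
  if (!is_count(C) || !is_count(N, min = 2L) || !is_number(fs) || fs <= 0)
    stopf("invalid epoch geometry: C = %s, N = %s, fs = %s",
          format(C), format(N), format(fs))
  stft_window <- as.integer(round(stft_window))
  stft_hop <- as.integer(round(stft_hop))
  if (stft_hop < 1L) stopf("'stft_hop' must be >= 1 sample")
  if (stft_window < 2L) stopf("'stft_window' must be >= 2 samples")
  if (stft_window > N)
    stopf("STFT window (%d) exceeds the epoch length (%d)", stft_window, N)
  if (length(conv_channels) != 4L || !all(vapply(conv_channels, is_count, TRUE)))
    stopf("'conv_channels' must be 4 positive integers (stem + 3 blocks)")
  conv_channels <- as.integer(conv_channels)
  if (!is_count(proj_hidden) || !is_count(proj_dim) || !is_count(head_hidden))
    stopf("projector/head sizes must be positive integers")
  nF <- stft_window %/% 2L + 1L
  nT <- stft_frame_count(N, stft_window, stft_hop)
  # spatial sizes through the three pooled blocks
  f <- nF; t <- nT
  for (b in 1:3) {
    f <- f %/% 2L; t <- t %/% 2L
    if (f < 1L || t < 1L)
      stopf(paste0("spectrogram grid %d x %d is too small for 3 pooled blocks; ",
                   "use a longer window or smaller hop"), nF, nT)
  }
  structure(list(C = as.integer(C), N = as.integer(N), fs = as.numeric(fs),
                 stft_window = stft_window, stft_hop = stft_hop,
                 stft_window_fn = stft_window_fn,
                 log_compress = isTRUE(log_compress),
                 normalize_input = isTRUE(normalize_input),
                 conv_channels = conv_channels,
                 repr_dim = conv_channels[4L],
                 proj_hidden = as.integer(proj_hidden),
                 proj_dim = as.integer(proj_dim),
                 head_hidden = as.integer(head_hidden),
                 n_freq = nF, n_frames = nT),
            class = "encoder_spec")
}

#' @export
print.encoder_spec <- function(x, ...) {
  cat(sprintf(paste0("<encoder_spec> %d ch x %d samples @ %g Hz | STFT %d/%d (%s)",
                     " -> %d x %d | conv %s -> d = %d | proj %d -> %d\n"),
              x$C, x$N, x$fs, x$stft_window, x$stft_hop, x$stft_window_fn,
              x$n_freq, x$n_frames,
              paste(x$conv_channels, collapse = "-"), x$repr_dim,
              x$proj_hidden, x$proj_dim))
  invisible(x)
}

# He-style scaled normal init for a 3x3 conv weight array (in -> out)
init_conv_w <- function(cin, cout) {
  array(rnorm(9L * cin * cout, sd = sqrt(2 / (9 * cin))),
        dim = c(3L, 3L, cin, cout))
}

init_linear <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

#' Initialize encoder and projector parameters
#'
#' Draws all weights from scaled normal distributions (He scaling for
#' convolutions, Glorot for linear layers) under the given seed, so any
#' experiment is reproducible from its seed alone.
#'
#' @param spec an [encoder_spec()].
#' @param seed integer seed.
#' @return A parameter list of class `encoder_params` with components
#'   `conv_w`, `conv_b` (lists over the 4 conv layers) and `proj`
#'   (`W1`, `b1`, `W2`, `b2`); the spec is attached as attribute
#'   `"spec"`.
#' @export
init_encoder <- function(spec, seed) {
  stopifnot(inherits(spec, "encoder_spec"))
  with_seed(seed, {
    widths <- c(spec$C, spec$conv_channels)
    conv_w <- lapply(1:4, function(l) init_conv_w(widths[l], widths[l + 1L]))
    conv_b <- lapply(1:4, function(l) numeric(widths[l + 1L]))
    proj <- list(W1 = init_linear(spec$repr_dim, spec$proj_hidden),
                 b1 = numeric(spec$proj_hidden),
                 W2 = init_linear(spec$proj_hidden, spec$proj_dim),
                 b2 = numeric(spec$proj_dim))
    params <- list(conv_w = conv_w, conv_b = conv_b, proj = proj)
    attr(params, "spec") <- spec
    class(params) <- "encoder_params"
    params
  })
}

params_spec <- function(params) {
  spec <- attr(params, "spec")
  if (is.null(spec)) stopf("parameters carry no encoder spec")
  spec
}

# accept a pretrain fit, a params list, or a checkpoint-like list
as_encoder_params <- function(encoder) {
  if (inherits(encoder, "contrawr_fit")) return(encoder$params)
  if (inherits(encoder, "encoder_params")) return(encoder)
  stopf("'encoder' must be encoder parameters or a pretrain fit")
}

# per-sample standardization of a spectrogram batch (F, T, C, n)
normalize_spect <- function(sp) {
  d <- dim(sp)
  m <- matrix(sp, ncol = d[4L])
  mu <- colMeans(m)
  sig <- sqrt(colMeans(m^2) - mu^2)
  sig[sig < 1e-12] <- 1
  m <- sweep(m, 2L, mu, "-")
  m <- sweep(m, 2L, sig, "/")
  array(m, dim = d)
}

# dataset/batch -> spectrogram array ready for the conv stack
spect_input <- function(signals, spec) {
  sp <- stft_batch(signals, spec$stft_window, spec$stft_hop,
                   spec$stft_window_fn, spec$log_compress)
  if (spec$normalize_input) sp <- normalize_spect(sp)
  sp
}

# same, from the N x (n*C) column layout used inside the training loop
spect_input_cols <- function(X, n, spec) {
  sp <- stft_cols(X, n, spec$C, spec$stft_window, spec$stft_hop,
                  spec$stft_window_fn, spec$log_compress)
  if (spec$normalize_input) sp <- normalize_spect(sp)
  sp
}

conv_weight_list <- function(params) params$conv_w
conv_bias_list <- function(params) params$conv_b

#' Encode epochs into d-dimensional representations
#'
#' Runs the frozen STFT + convolutional stack on one epoch
#' (`encode()`) or a whole dataset (`encode_batch()`).  Encoding is a
#' pure function of the epoch and the parameters: no randomness is
#' involved at inference.
#'
#' @param x a [signal_epoch()].
#' @param params an `encoder_params` object (or a pretrain fit).
#' @return `encode()`: a numeric vector `h` of length `d`;
#'   `encode_batch()`: an `n x d` matrix.
#' @export
encode <- function(x, params) {
  stopifnot(inherits(x, "signal_epoch"))
  params <- as_encoder_params(params)
  spec <- params_spec(params)
  if (nrow(x$data) != spec$C || ncol(x$data) != spec$N)
    stopf("epoch is %d x %d but the encoder expects %d x %d",
          nrow(x$data), ncol(x$data), spec$C, spec$N)
  sig <- array(x$data, dim = c(1L, dim(x$data)))
  drop(encode_signals(sig, params, spec))
}

#' @rdname encode
#' @param ds an [epoch_dataset()] (or a bare `n x C x N` array).
#' @param chunk number of epochs encoded per chunk (bounds memory).
#' @export
encode_batch <- function(ds, params, chunk = 128L) {
  params <- as_encoder_params(params)
  spec <- params_spec(params)
  signals <- if (inherits(ds, "epoch_dataset")) ds$signals else ds
  if (!is.array(signals) || length(dim(signals)) != 3L)
    stopf("'ds' must be an epoch_dataset or a 3-d array")
  if (dim(signals)[2L] != spec$C || dim(signals)[3L] != spec$N)
    stopf("epochs are %d x %d but the encoder expects %d x %d",
          dim(signals)[2L], dim(signals)[3L], spec$C, spec$N)
  n <- dim(signals)[1L]
  out <- matrix(0, n, spec$repr_dim)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    out[idx, ] <- encode_signals(signals[idx, , , drop = FALSE], params, spec)
  }
  out
}

encode_signals <- function(signals, params, spec) {
  sp <- spect_input(signals, spec)
  fw <- cnn_forward_cpp(sp, conv_weight_list(params), conv_bias_list(params),
                        FALSE)
  fw$h
}

#' Project a representation onto the unit hypersphere
#'
#' Applies the 2-layer projector g(.) and L2-normalizes the output, so
#' every projection lies on the unit sphere of dimension `proj_dim`.
#' Batch averages of projections then lie inside the closed unit ball,
#' the domain of the Gaussian-kernel similarity.
#'
#' @param h numeric vector of length `d`, or an `n x d` matrix of
#'   representations.
#' @param params an `encoder_params` object (or a pretrain fit).
#' @return A unit-norm vector of length `proj_dim` (or an `n x proj_dim`
#'   matrix of unit rows).
#' @export
project <- function(h, params) {
  params <- as_encoder_params(params)
  spec <- params_spec(params)
  H <- if (is.matrix(h)) h else matrix(h, nrow = 1L)
  if (ncol(H) != spec$repr_dim)
    stopf("representation length %d does not match d = %d", ncol(H), spec$repr_dim)
  Z <- mlp_forward(H, params$proj, normalize = TRUE)$Z
  if (is.matrix(h)) Z else drop(Z)
}

#' Save or load an encoder checkpoint
#'
#' A checkpoint stores the parameters together with their
#' [encoder_spec()], and loading verifies that the stored spec matches
#' any expectation supplied, so a checkpoint can never silently be
#' applied to epochs of the wrong geometry.
#'
#' @param params an `encoder_params` object (or a pretrain fit, whose
#'   online parameters are stored).
#' @param path file path.
#' @return `load_checkpoint()` returns the `encoder_params`.
#' @export
save_checkpoint <- function(params, path) {
  params <- as_encoder_params(params)
  saveRDS(list(format = "contrawr-checkpoint", version = 1L,
               spec = params_spec(params), params = unclass(params)),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expected_spec optional [encoder_spec()]; loading fails if the
#'   checkpoint was built for a different architecture or epoch geometry.
#' @export
load_checkpoint <- function(path, expected_spec = NULL) {
  if (!file.exists(path)) stopf("checkpoint '%s' does not exist", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "contrawr-checkpoint"))
    stopf("'%s' is not a contrawr checkpoint", path)
  if (!is.null(expected_spec) && !identical(unclass(obj$spec),
                                            unclass(expected_spec)))
    stopf("checkpoint spec does not match the expected encoder spec")
  params <- obj$params
  attr(params, "spec") <- obj$spec
  class(params) <- "encoder_params"
  params
}
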