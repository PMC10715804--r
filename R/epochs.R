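#' Construct a single signal epoch
#'
#' A signal epoch is one fixed-length window of a multichannel recording:
#' a C x N real matrix (channels x samples) with its sampling rate and an
#' optional integer stage label.  It is the unit sample of every operation
#' in the package.
#'
#' @param data real matrix with C >= 1 rows (channels) and N >= 2 columns
#'   (samples); all values must be finite.
#' @param fs sampling rate in Hz (> 0).
#' @param label optional integer class label (e.g. sleep stage coded
#'   0 = W, 1 = N1, 2 = N2, 3 = N3, 4 = R), or `NULL` when unlabeled.
#' @return An object of class `signal_epoch`: a list with elements
#'   `data`, `fs` and `label`.
#' @examples
#' x <- signal_epoch(matrix(rnorm(2 * 100), 2, 100), fs = 50)
#' dim(x$data)
#' @export
signal_epoch <- function(data, fs, label = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stopf("'data' must be a numeric matrix (channels x samples)")
  if (nrow(data) < 1L || ncol(data) < 2L)
    stopf("epoch must have C >= 1 channels and N >= 2 samples, got %d x %d",
          nrow(data), ncol(data))
  if (!all(is.finite(data)))
    stopf("epoch contains non-finite values")
  if (!is_number(fs) || fs <= 0)
    stopf("'fs' must be a positive number, got %s", format(fs))
  if (!is.null(label)) {
    if (!is_count(label, min = 0L)) stopf("'label' must be a single non-negative integer")
    label <- as.integer(label)
  }
  structure(list(data = data, fs = as.numeric(fs), label = label),
            class = "signal_epoch")
}

#' @export
print.signal_epoch <- function(x, ...) {
  cat(sprintf("<signal_epoch> %d channels x %d samples @ %g Hz%s\n",
              nrow(x$data), ncol(x$data), x$fs,
              if (is.null(x$label)) ", unlabeled"
              else sprintf(", label %d", x$label)))
  invisible(x)
}

#' Construct a dataset of signal epochs
#'
#' Groups epochs that share a channel layout, length and sampling rate
#' into one container, together with subject identifiers (so splits can
#' be made at the subject level) and optional labels.
#'
#' @param signals numeric array of dimension `c(n, C, N)`: n epochs of C
#'   channels x N samples.
#' @param fs sampling rate in Hz.
#' @param subject character vector of length n; the subject each epoch
#'   was recorded from.
#' @param labels optional integer vector of length n with class codes in
#'   `0..K-1`, or `NULL` for an unlabeled set.
#' @param channel_names optional character vector of length C.
#' @return An object of class `epoch_dataset`.
#' @seealso [get_epoch()], [subset_epochs()], [generate_dataset()]
#' @export
epoch_dataset <- function(signals, fs, subject, labels = NULL,
                          channel_names = NULL) {
  if (!is.array(signals) || length(dim(signals)) != 3L)
    stopf("'signals' must be a 3-d array (epochs x channels x samples)")
  n <- dim(signals)[1L]; C <- dim(signals)[2L]; N <- dim(signals)[3L]
  if (C < 1L || N < 2L)
    stopf("epochs must have C >= 1 channels and N >= 2 samples")
  if (!all(is.finite(signals))) stopf("signals contain non-finite values")
  if (!is_number(fs) || fs <= 0) stopf("'fs' must be a positive number")
  subject <- as.character(subject)
  if (length(subject) != n)
    stopf("'subject' must have one id per epoch (%d), got %d", n, length(subject))
  if (!is.null(labels)) {
    if (length(labels) != n)
      stopf("'labels' must have length %d, got %d", n, length(labels))
    if (any(!is.finite(labels)) || any(labels != round(labels)) || any(labels < 0))
      stopf("'labels' must be non-negative integers")
    labels <- as.integer(labels)
  }
  if (is.null(channel_names)) channel_names <- sprintf("ch%d", seq_len(C))
  if (length(channel_names) != C)
    stopf("'channel_names' must have length %d", C)
  structure(list(signals = signals, fs = as.numeric(fs), subject = subject,
                 labels = labels, channel_names = as.character(channel_names)),
            class = "epoch_dataset")
}

#' @export
print.epoch_dataset <- function(x, ...) {
  d <- dim(x$signals)
  cat(sprintf("<epoch_dataset> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$fs))
  cat(sprintf("  subjects: %d; labels: %s\n", length(unique(x$subject)),
              if (is.null(x$labels)) "absent"
              else paste0(length(unique(x$labels)), " classes")))
  invisible(x)
}

#' Number of epochs in a dataset
#' @param ds an `epoch_dataset`.
#' @return Integer count of epochs.
#' @export
n_epochs <- function(ds) dim(ds$signals)[1L]

#' Extract one epoch from a dataset
#' @param ds an `epoch_dataset`.
#' @param i epoch index.
#' @return A [signal_epoch()].
#' @export
get_epoch <- function(ds, i) {
  n <- n_epochs(ds)
  if (!is_count(i) || i > n) stopf("epoch index %s out of range 1..%d", format(i), n)
  dat <- ds$signals[i, , , drop = FALSE]
  dim(dat) <- dim(ds$signals)[2:3]
  signal_epoch(dat, ds$fs,
               label = if (is.null(ds$labels)) NULL else ds$labels[i])
}

#' Subset a dataset by epoch index
#' @param ds an `epoch_dataset`.
#' @param idx integer vector of epoch indices to keep.
#' @return An `epoch_dataset` with the selected epochs.
#' @export
subset_epochs <- function(ds, idx) {
  idx <- as.integer(idx)
  if (length(idx) == 0L) stopf("cannot subset to an empty dataset")
  if (any(idx < 1L | idx > n_epochs(ds))) stopf("epoch index out of range")
  epoch_dataset(ds$signals[idx, , , drop = FALSE], ds$fs,
                ds$subject[idx],
                labels = if (is.null(ds$labels)) NULL else ds$labels[idx],
                channel_names = ds$channel_names)
}

#' Drop the labels of a dataset
#'
#' Used before self-supervised pretraining, which must never read labels.
#' @param ds an `epoch_dataset`.
#' @return The same dataset with `labels = NULL`.
#' @export
strip_labels <- function(ds) {
  ds$labels <- NULL
  ds
}
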