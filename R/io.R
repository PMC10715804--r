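# Epoch container I/O and EDF ingestion.

#' Write an epoch dataset to a container file
#'
#' Serializes the dataset (signals, sampling rate, subjects, optional
#' labels, channel names) to a single versioned container file that
#' [read_epochs()] validates on load, so synthetic and recorded data
#' travel through the same path.
#'
#' @param ds an [epoch_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(ds, path) {
  stopifnot(inherits(ds, "epoch_dataset"))
  saveRDS(list(format = "contrawr-epochs", version = 1L,
               fs = ds$fs, channel_names = ds$channel_names,
               subject = ds$subject, labels = ds$labels,
               signals = ds$signals),
          path)
  invisible(path)
}

#' Read an epoch dataset from a container file
#'
#' Validates the container layout and the shape of every epoch;
#' validation errors name the offending record.  A container without
#' labels yields `labels = NULL` (absent, not zero).
#'
#' @param path file written by [write_epochs()].
#' @return An [epoch_dataset()].
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stopf("file '%s' does not exist", path)
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "contrawr-epochs"))
    stopf("'%s' is not an epoch container", path)
  sig <- obj$signals
  if (is.list(sig)) {
    # list-of-matrices layout: validate shapes epoch by epoch
    if (!length(sig)) stopf("container holds no epochs")
    C <- nrow(sig[[1L]]); N <- ncol(sig[[1L]])
    for (i in seq_along(sig)) {
      if (!is.matrix(sig[[i]]))
        stopf("epoch %d is not a matrix", i)
      if (nrow(sig[[i]]) != C || ncol(sig[[i]]) != N)
        stopf("epoch %d has shape %d x %d, expected %d x %d",
              i, nrow(sig[[i]]), ncol(sig[[i]]), C, N)
    }
    arr <- array(0, dim = c(length(sig), C, N))
    for (i in seq_along(sig)) arr[i, , ] <- sig[[i]]
    sig <- arr
  }
  if (!is.array(sig) || length(dim(sig)) != 3L)
    stopf("container signals must be a 3-d array or a list of matrices")
  epoch_dataset(sig, obj$fs, obj$subject, labels = obj$labels,
                channel_names = obj$channel_names)
}

read_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' Read an EDF recording and segment it into epochs
#'
#' Minimal reader for European Data Format files (ASCII headers,
#' little-endian 16-bit records, digital-to-physical scaling).  The
#' selected channels, which must share one sampling rate, are
#' concatenated across data records and sliced into disjoint
#' non-overlapping windows of `epoch_seconds`; a trailing partial window
#' is dropped.
#'
#' @param path EDF file path.
#' @param channel_names channels to extract, or `NULL` for all.
#' @param epoch_seconds window length in seconds (default 30, the
#'   standard sleep-staging epoch).
#' @return An unlabeled [epoch_dataset()] whose subject id is the file
#'   name.
#' @export
read_edf <- function(path, channel_names = NULL, epoch_seconds = 30) {
  if (!file.exists(path)) stopf("file '%s' does not exist", path)
  con <- file(path, "rb")
  on.exit(close(con))
  read_ascii(con, 8L)                      # version
  read_ascii(con, 80L); read_ascii(con, 80L)  # patient / recording ids
  read_ascii(con, 8L); read_ascii(con, 8L)    # start date / time
  read_ascii(con, 8L)                      # header length
  read_ascii(con, 44L)                     # reserved
  n_rec <- as.integer(read_ascii(con, 8L))
  rec_dur <- as.numeric(read_ascii(con, 8L))
  ns <- as.integer(read_ascii(con, 4L))
  if (!isTRUE(ns >= 1L)) stopf("'%s' declares no signals", path)
  labels <- vapply(seq_len(ns), function(i) read_ascii(con, 16L), "")
  for (i in seq_len(ns)) read_ascii(con, 80L)  # transducer
  for (i in seq_len(ns)) read_ascii(con, 8L)   # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8L)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8L)), 0)
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8L)), 0)
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8L)), 0)
  for (i in seq_len(ns)) read_ascii(con, 80L)  # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(read_ascii(con, 8L)), 0L)
  for (i in seq_len(ns)) read_ascii(con, 32L)  # reserved

  if (is.null(channel_names)) channel_names <- labels
  sel <- match(channel_names, labels)
  if (anyNA(sel))
    stopf("channel '%s' not found; available: %s",
          channel_names[which(is.na(sel))[1L]],
          paste(labels, collapse = ", "))
  if (length(unique(spr[sel])) != 1L)
    stopf("selected channels have different sampling rates")
  fs <- spr[sel[1L]] / rec_dur

  chunks <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    rec <- vector("list", ns)
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      rec[[i]] <- dig
    }
    chunks[[r]] <- rec
  }
  C <- length(sel)
  total <- n_rec * spr[sel[1L]]
  sig <- matrix(0, C, total)
  for (j in seq_along(sel)) {
    i <- sel[j]
    dig <- unlist(lapply(chunks, `[[`, i), use.names = FALSE)
    g <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
    sig[j, ] <- (dig - dmin_[i]) * g + pmin_[i]
  }
  Nep <- as.integer(round(epoch_seconds * fs))
  n_ep <- total %/% Nep
  if (n_ep < 1L)
    stopf("recording (%d samples) is shorter than one %g-s epoch",
          total, epoch_seconds)
  arr <- array(0, dim = c(n_ep, C, Nep))
  for (e in seq_len(n_ep)) {
    arr[e, , ] <- sig[, ((e - 1L) * Nep + 1L):(e * Nep), drop = FALSE]
  }
  epoch_dataset(arr, fs, rep(basename(path), n_ep),
                channel_names = channel_names)
}
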