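# Independent EDF writer used only to build test fixtures: follows the
# European Data Format layout (256-byte ASCII header + 256 bytes per
# signal, then little-endian 16-bit data records) without touching the
# package's reader.

pad <- function(x, n) {
  s <- as.character(x)
  if (nchar(s) > n) s <- substr(s, 1, n)
  sprintf(paste0("%-", n, "s"), s)
}

write_edf_fixture <- function(path, channels, fs, record_seconds = 1,
                              phys_range = c(-50, 50)) {
  ns <- length(channels)
  len <- unique(vapply(channels, length, 0L))
  stopifnot(length(len) == 1L)
  spr <- as.integer(fs * record_seconds)
  n_rec <- len %/% spr
  dmin <- -32768; dmax <- 32767
  pmin <- phys_range[1]; pmax <- phys_range[2]

  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s) writeChar(s, con, eos = NULL)
  put(pad("0", 8))
  put(pad("synthetic patient", 80))
  put(pad("synthetic recording", 80))
  put(pad("01.01.20", 8)); put(pad("00.00.00", 8))
  put(pad(256L * (1L + ns), 8))
  put(pad("", 44))
  put(pad(n_rec, 8))
  put(pad(format(record_seconds), 8))
  put(pad(ns, 4))
  for (nm in names(channels)) put(pad(nm, 16))
  for (i in seq_len(ns)) put(pad("synthetic", 80))
  for (i in seq_len(ns)) put(pad("uV", 8))
  for (i in seq_len(ns)) put(pad(format(pmin), 8))
  for (i in seq_len(ns)) put(pad(format(pmax), 8))
  for (i in seq_len(ns)) put(pad(format(dmin), 8))
  for (i in seq_len(ns)) put(pad(format(dmax), 8))
  for (i in seq_len(ns)) put(pad("none", 80))
  for (i in seq_len(ns)) put(pad(spr, 8))
  for (i in seq_len(ns)) put(pad("", 32))

  to_dig <- function(x) {
    d <- round((x - pmin) / (pmax - pmin) * (dmax - dmin) + dmin)
    as.integer(pmin(pmax(d, dmin), dmax))
  }
  for (r in seq_len(n_rec)) {
    for (ch in channels) {
      seg <- ch[((r - 1L) * spr + 1L):(r * spr)]
      writeBin(to_dig(seg), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
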