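# Minimal EDF (European Data Format) reader/writer: 16-bit integer samples,
# identical record layout for every channel, no annotation channels.

pad <- function(s, n) {
  s <- substr(s, 1, n)
  formatC(s, width = -n, flag = " ")
}

# smallest decimal resolution (uV per digital unit) that covers the data
edf_resolution <- function(max_abs) {
  res <- 0.01
  while (max_abs > 32767 * res) res <- res * 10
  res
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to the 16-bit EDF grid with a per-file decimal
#' resolution (0.01 uV or the smallest power-of-ten multiple covering the
#' data). Bad-channel flags and reference state are not representable in EDF
#' and are dropped; record duration is 1 s when the length allows, otherwise
#' a single record spans the file.
#'
#' @param rec a [raw_recording()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  x <- rec$samples
  ns <- nrow(x)
  fs <- rec$sampling_rate
  nt <- ncol(x)
  if (fs == round(fs) && nt %% fs == 0) {
    n_rec <- nt / fs
    spr <- as.integer(fs)
    dur <- 1
  } else {
    n_rec <- 1L
    spr <- nt
    dur <- nt / fs
  }
  res <- edf_resolution(max(abs(x), 1e-6))
  pmin <- -32768 * res
  pmax <- 32767 * res
  dig <- round(x / res)
  dig[dig > 32767] <- 32767
  dig[dig < -32768] <- -32768
  storage.mode(dig) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, n) writeChar(pad(s, n), con, nchars = n, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr("Startdate X X X X", 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(as.character(256 * (ns + 1)), 8)
  wr("", 44)
  wr(as.character(n_rec), 8)
  wr(format(dur, digits = 7), 8)
  wr(as.character(ns), 4)
  for (lab in rec$channel_labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(format(pmin, digits = 7), 8)
  for (i in seq_len(ns)) wr(format(pmax, digits = 7), 8)
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(as.character(spr), 8)
  for (i in seq_len(ns)) wr("", 32)
  for (r in seq_len(n_rec)) {
    sl <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns)) {
      writeBin(dig[ch, sl], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Supports plain EDF with a common record layout across channels. Channels
#' with differing sampling rates (different samples-per-record) are rejected.
#'
#' @param path EDF file path.
#' @return a [raw_recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) {
    stop_swatopo(sprintf("EDF file not found: %s", path), "swatopo_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    s <- readChar(con, n, useBytes = TRUE)
    if (nchar(s, type = "bytes") < n) {
      stop_swatopo("truncated EDF header.", "swatopo_format_error")
    }
    trimws(s)
  }
  version <- rd(8)
  if (version != "0") {
    stop_swatopo(sprintf("not an EDF file (version field '%s').", version),
                 "swatopo_format_error")
  }
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || is.na(dur) || dur <= 0) {
    stop_swatopo("unreadable EDF header fields.", "swatopo_format_error")
  }
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L) {
    stop_swatopo("channels with differing sampling rates are not supported.",
                 "swatopo_unsupported_error")
  }
  if (anyDuplicated(labels)) {
    stop_swatopo("duplicated channel label in EDF header.",
                 "swatopo_format_error")
  }
  if (header_bytes != 256 * (ns + 1)) {
    stop_swatopo("inconsistent EDF header size.", "swatopo_format_error")
  }
  spr <- spr[1]
  fs <- spr / dur
  x <- matrix(0, nrow = ns, ncol = n_rec * spr)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr, size = 2, endian = "little")
      if (length(dig) < spr) {
        stop_swatopo("truncated EDF data section.", "swatopo_format_error")
      }
      x[ch, ((r - 1) * spr + 1):(r * spr)] <-
        pmin[ch] + (dig - dmin[ch]) * scale[ch]
    }
  }
  raw_recording(x, labels, fs)
}
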