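# Minimal BrainVision triplet (.vhdr/.vmrk/.eeg) reader/writer:
# binary IEEE float32, multiplexed orientation.

bv_paths <- function(vhdr_path) {
  base <- sub("\\.vhdr$", "", vhdr_path)
  list(vhdr = vhdr_path, vmrk = paste0(base, ".vmrk"),
       eeg = paste0(base, ".eeg"))
}

#' Write a recording as a BrainVision triplet
#'
#' Writes `<base>.vhdr`, `<base>.vmrk` and `<base>.eeg` with multiplexed
#' IEEE float32 data in microvolts (resolution 1). Samples are rounded to
#' float32 precision.
#'
#' @param rec a [raw_recording()].
#' @param vhdr_path path of the header file (must end in `.vhdr`).
#' @return the header path, invisibly.
#' @export
write_brainvision <- function(rec, vhdr_path) {
  stopifnot(inherits(rec, "raw_recording"))
  p <- bv_paths(vhdr_path)
  ns <- nrow(rec$samples)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    sprintf("DataFile=%s", basename(p$eeg)),
    sprintf("MarkerFile=%s", basename(p$vmrk)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", ns),
    sprintf("SamplingInterval=%.10g", 1e6 / rec$sampling_rate),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(ns), rec$channel_labels)
  )
  writeLines(hdr, p$vhdr, useBytes = TRUE)
  writeLines(c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    sprintf("DataFile=%s", basename(p$eeg)),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000"
  ), p$vmrk)
  con <- file(p$eeg, "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$samples), con, size = 4, endian = "little")
  invisible(vhdr_path)
}

bv_parse_ini <- function(lines) {
  kv <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" || startsWith(ln, ";") || startsWith(ln, "[")) next
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq > 0) {
      kv[[substr(ln, 1, eq - 1)]] <- substr(ln, eq + 1, nchar(ln))
    }
  }
  kv
}

#' Read a BrainVision triplet
#'
#' Expects binary multiplexed IEEE float32 or 16-bit integer data. All three
#' files of the triplet must be present; a missing component is reported by
#' name.
#'
#' @param vhdr_path path of the `.vhdr` header file.
#' @return a [raw_recording()].
#' @export
read_brainvision <- function(vhdr_path) {
  p <- bv_paths(vhdr_path)
  if (!file.exists(p$vhdr)) {
    stop_swatopo(sprintf("missing BrainVision component: %s", p$vhdr),
                 "swatopo_io_error")
  }
  lines <- readLines(p$vhdr, warn = FALSE)
  kv <- bv_parse_ini(lines)
  datafile <- file.path(dirname(p$vhdr), kv$DataFile %||% basename(p$eeg))
  markerfile <- file.path(dirname(p$vhdr), kv$MarkerFile %||% basename(p$vmrk))
  for (f in c(markerfile, datafile)) {
    if (!file.exists(f)) {
      stop_swatopo(sprintf("missing BrainVision component: %s", f),
                   "swatopo_io_error")
    }
  }
  if (!identical(kv$DataFormat, "BINARY") ||
      !identical(kv$DataOrientation, "MULTIPLEXED")) {
    stop_swatopo("only binary multiplexed BrainVision data are supported.",
                 "swatopo_unsupported_error")
  }
  ns <- as.integer(kv$NumberOfChannels)
  si <- as.numeric(kv$SamplingInterval)
  if (is.na(ns) || ns < 1 || is.na(si) || si <= 0) {
    stop_swatopo("unreadable BrainVision header fields.",
                 "swatopo_format_error")
  }
  fs <- 1e6 / si
  labels <- character(ns)
  resol <- rep(1, ns)
  for (i in seq_len(ns)) {
    entry <- kv[[sprintf("Ch%d", i)]]
    if (is.null(entry)) {
      stop_swatopo(sprintf("channel Ch%d missing from BrainVision header.", i),
                   "swatopo_format_error")
    }
    parts <- strsplit(entry, ",", fixed = TRUE)[[1]]
    labels[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) resol[i] <- as.numeric(parts[3])
  }
  if (anyDuplicated(labels)) {
    stop_swatopo("duplicated channel label in BrainVision header.",
                 "swatopo_format_error")
  }
  fmt <- kv$BinaryFormat %||% "IEEE_FLOAT_32"
  sz <- file.info(datafile)$size
  if (identical(fmt, "IEEE_FLOAT_32")) {
    n <- sz / 4
    con <- file(datafile, "rb")
    on.exit(close(con))
    raw_vals <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  } else if (identical(fmt, "INT_16")) {
    n <- sz / 2
    con <- file(datafile, "rb")
    on.exit(close(con))
    raw_vals <- readBin(con, "integer", n = n, size = 2, endian = "little")
  } else {
    stop_swatopo(sprintf("unsupported BinaryFormat '%s'.", fmt),
                 "swatopo_unsupported_error")
  }
  if (length(raw_vals) %% ns != 0) {
    stop_swatopo("BrainVision data size is not a multiple of channel count.",
                 "swatopo_format_error")
  }
  x <- matrix(raw_vals, nrow = ns) * resol
  raw_recording(x, labels, fs)
}
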