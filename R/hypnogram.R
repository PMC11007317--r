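#' Hypnograms
#'
#' An ordered sequence of visually scored sleep stages, one per fixed-length
#' epoch (30 s by default), with lights-off and wake-up epoch indices
#' delimiting time in bed. Indices are 0-based and intervals half-open
#' `[lights_off, wake_up)`.
#'
#' @param stages character vector over `c("W","N1","N2","N3","REM")`.
#' @param epoch_length epoch duration in seconds (default 30).
#' @param lights_off 0-based index of the first in-bed epoch (default 0).
#' @param wake_up 0-based one-past-the-end index of time in bed (default
#'   `length(stages)`).
#' @return a `hypnogram` object.
#' @export
hypnogram <- function(stages, epoch_length = 30, lights_off = 0L,
                      wake_up = length(stages)) {
  stages <- as.character(stages)
  if (length(stages) == 0L) {
    stop_swatopo("hypnogram must contain at least one epoch.",
                 "swatopo_format_error")
  }
  bad <- which(!stages %in% STAGES)
  if (length(bad)) {
    stop_swatopo(
      sprintf("unknown stage token '%s' at epoch %d.", stages[bad[1]], bad[1]),
      "swatopo_parse_error"
    )
  }
  assert_scalar_number(epoch_length, "epoch_length")
  if (epoch_length <= 0) {
    stop_swatopo("epoch_length must be positive.", "swatopo_parameter_error")
  }
  lights_off <- as.integer(lights_off)
  wake_up <- as.integer(wake_up)
  if (!(0L <= lights_off && lights_off <= wake_up &&
        wake_up <= length(stages))) {
    stop_swatopo("need 0 <= lights_off <= wake_up <= length(stages).",
                 "swatopo_format_error")
  }
  structure(
    list(stages = stages, epoch_length = epoch_length,
         lights_off = lights_off, wake_up = wake_up),
    class = "hypnogram"
  )
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram: %d x %gs epochs (%.1f min), in bed [%d, %d)>\n",
              length(x$stages), x$epoch_length,
              length(x$stages) * x$epoch_length / 60, x$lights_off, x$wake_up))
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$stages)

# stage tokens accepted on input and their canonical form
STAGE_ALIASES <- c(
  "W" = "W", "0" = "W", "WAKE" = "W",
  "N1" = "N1", "1" = "N1",
  "N2" = "N2", "2" = "N2",
  "N3" = "N3", "3" = "N3",
  "REM" = "REM", "R" = "REM", "5" = "REM"
)

#' Read / write a plain-text hypnogram
#'
#' One stage token per line. Tokens `W/N1/N2/N3/REM` and the aliases
#' `0/1/2/3` and `R`/`5` (for REM) are accepted. Optional `#`-prefixed header
#' lines `# epoch_length: <s>`, `# lights_off: <epoch>` and
#' `# wake_up: <epoch>` override the defaults (whole file in bed, 30-s
#' epochs).
#'
#' @param path file path.
#' @return `read_hypnogram()` a [hypnogram()]; `write_hypnogram()` the path,
#'   invisibly.
#' @export
read_hypnogram <- function(path) {
  if (!file.exists(path)) {
    stop_swatopo(sprintf("hypnogram file not found: %s", path),
                 "swatopo_io_error")
  }
  lines <- readLines(path)
  hdr <- list()
  stages <- character()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      kv <- strsplit(sub("^#\\s*", "", ln), ":")[[1]]
      if (length(kv) == 2) hdr[[trimws(kv[1])]] <- as.numeric(trimws(kv[2]))
      next
    }
    tok <- toupper(ln)
    if (!tok %in% names(STAGE_ALIASES)) {
      stop_swatopo(sprintf("unknown stage token '%s' at line %d of %s.",
                           ln, i, path),
                   "swatopo_parse_error")
    }
    stages <- c(stages, STAGE_ALIASES[[tok]])
  }
  if (length(stages) == 0L) {
    stop_swatopo(sprintf("hypnogram file %s contains no epochs.", path),
                 "swatopo_parse_error")
  }
  hypnogram(
    stages,
    epoch_length = hdr$epoch_length %||% 30,
    lights_off = hdr$lights_off %||% 0L,
    wake_up = hdr$wake_up %||% length(stages)
  )
}

#' @rdname read_hypnogram
#' @param hyp a [hypnogram()].
#' @export
write_hypnogram <- function(hyp, path) {
  hdr <- c(
    sprintf("# epoch_length: %g", hyp$epoch_length),
    sprintf("# lights_off: %d", hyp$lights_off),
    sprintf("# wake_up: %d", hyp$wake_up)
  )
  writeLines(c(hdr, hyp$stages), path)
  invisible(path)
}

# stages of the in-bed portion
in_bed_stages <- function(hyp) {
  if (hyp$wake_up == hyp$lights_off) return(character())
  hyp$stages[(hyp$lights_off + 1L):hyp$wake_up]
}
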