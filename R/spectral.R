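#' Frequency band
#'
#' Inclusive frequency-bin range in Hz. The slow-wave activity band is
#' 0.8-4.6 Hz; the high-frequency artifact screening band is 20-40 Hz.
#'
#' @param low,high band edges in Hz, `0 <= low < high`.
#' @return a `band` object.
#' @export
band <- function(low, high) {
  assert_scalar_number(low, "low", lower = 0)
  assert_scalar_number(high, "high")
  if (low >= high) {
    stop_swatopo("band requires low < high.", "swatopo_parameter_error")
  }
  structure(list(low = low, high = high), class = "band")
}

#' @export
print.band <- function(x, ...) {
  cat(sprintf("<band: %g-%g Hz>\n", x$low, x$high))
  invisible(x)
}

#' @rdname band
#' @export
swa_band <- function() band(0.8, 4.6)

#' @rdname band
#' @export
artifact_band <- function() band(20, 40)

#' Per-channel power spectrum of one epoch
#'
#' The epoch is split into non-overlapping subepochs (5 s by default, giving
#' 0.2 Hz bin spacing), each subepoch is demeaned and Hanning-windowed, and
#' the window-power-corrected one-sided periodograms are averaged. The
#' scaling is such that a sinusoid of amplitude A at a bin centre contributes
#' total power A^2/2 (uV^2) and the bin sum matches the time-domain mean
#' square (Parseval). The 0 Hz bin holds the squared subepoch mean.
#'
#' @param x channel x sample matrix (uV) spanning one epoch.
#' @param sampling_rate Hz.
#' @param subepoch_s subepoch length in seconds; the epoch must be an exact
#'   multiple.
#' @return list with `freq` (Hz) and `power` (channel x bin matrix, uV^2).
#' @export
epoch_psd <- function(x, sampling_rate, subepoch_s = 5) {
  x <- rbind(x)
  nt <- ncol(x)
  nsub <- sampling_rate * subepoch_s
  if (abs(nsub - round(nsub)) > 1e-9 || nt %% round(nsub) != 0) {
    stop_swatopo("epoch length must be an exact multiple of the subepoch.",
                 "swatopo_parameter_error")
  }
  nsub <- as.integer(round(nsub))
  k <- nt / nsub
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nsub - 1)) / nsub)  # periodic Hann
  s2 <- sum(w^2)
  nbin <- nsub %/% 2 + 1
  freq <- (0:(nbin - 1)) / subepoch_s
  acc <- matrix(0, nrow(x), nbin)
  for (s in seq_len(k)) {
    seg <- x[, ((s - 1) * nsub + 1):(s * nsub), drop = FALSE]
    mu <- rowMeans(seg)
    seg <- (seg - mu) * rep(w, each = nrow(seg))
    X <- t(stats::mvfft(t(seg)))
    p <- Mod(X[, seq_len(nbin), drop = FALSE])^2 / (nsub * s2)
    dbl <- 2:(nbin - if (nsub %% 2 == 0) 1 else 0)
    p[, dbl] <- 2 * p[, dbl]
    # 0 Hz bin: squared subepoch mean plus the residual windowed DC power,
    # so the bin sum satisfies Parseval exactly
    p[, 1] <- mu^2 + p[, 1]
    acc <- acc + p
  }
  list(freq = freq, power = acc / k)
}

#' Band power from a spectrum
#'
#' Sum of the power in all bins whose centre frequency f satisfies
#' `low <= f <= high` (inclusive; with 0.2 Hz bins, 0.8 and 4.6 Hz are bin
#' centres).
#'
#' @param spectrum list as returned by [epoch_psd()].
#' @param bd a [band()].
#' @return numeric vector, one total power (uV^2) per channel.
#' @export
band_power <- function(spectrum, bd) {
  f <- spectrum$freq
  if (bd$low > max(f) || bd$high < min(f)) {
    stop_swatopo("band lies outside the spectrum range.",
                 "swatopo_parameter_error")
  }
  sel <- f >= bd$low - 1e-9 & f <= bd$high + 1e-9
  rowSums(spectrum$power[, sel, drop = FALSE])
}

#' Per-epoch band power for an epoched recording
#'
#' Runs [epoch_psd()] and [band_power()] over every epoch.
#'
#' @param epochs an [epoched_recording()].
#' @param bd a [band()].
#' @param subepoch_s subepoch length in seconds.
#' @return an `epoch_band_power` object: `power` (epoch x channel matrix,
#'   uV^2), `band`, `epoch_stage`, `artifact` (all `FALSE` initially),
#'   `channel_labels`, `bad_channels`.
#' @export
epoch_band_power <- function(epochs, bd, subepoch_s = 5) {
  stopifnot(inherits(epochs, "epoched_recording"))
  n_ep <- dim(epochs$epochs)[1]
  pw <- matrix(0, n_ep, length(epochs$channel_labels))
  for (e in seq_len(n_ep)) {
    sp <- epoch_psd(epochs$epochs[e, , , drop = TRUE], epochs$sampling_rate,
                    subepoch_s)
    pw[e, ] <- band_power(sp, bd)
  }
  colnames(pw) <- epochs$channel_labels
  structure(
    list(power = pw, band = bd, epoch_stage = epochs$epoch_stage,
         artifact = rep(FALSE, n_ep), channel_labels = epochs$channel_labels,
         bad_channels = epochs$bad_channels),
    class = "epoch_band_power"
  )
}

#' @export
print.epoch_band_power <- function(x, ...) {
  cat(sprintf("<epoch_band_power: %d epochs x %d channels, %g-%g Hz, %d flagged>\n",
              nrow(x$power), ncol(x$power), x$band$low, x$band$high,
              sum(x$artifact)))
  invisible(x)
}

# centered moving average with shrunk edges, window w (odd)
moving_average <- function(x, w) {
  n <- length(x)
  half <- (w - 1) / 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, 0)
}

#' Semiautomatic artifact screening
#'
#' An epoch is flagged when its power, averaged over good channels, exceeds
#' `factor` times a centred moving average (over `window` epochs, edges
#' shrunk) in either the slow-wave band or the high-frequency band. Moving
#' averages are computed within stage class (NREM vs REM/wake) so stage
#' transitions do not masquerade as artifacts. Flagged epochs are excluded
#' from all downstream averaging; the accompanying report supports manual
#' review.
#'
#' @param swa,hf `epoch_band_power` objects for the 0.8-4.6 and 20-40 Hz
#'   bands over the same epochs.
#' @param window moving-average length in epochs (odd, >= 3; default 15).
#' @param factor_swa,factor_hf threshold multipliers (defaults 2.0 and 2.5).
#' @return logical vector, `TRUE` for flagged epochs, with an
#'   `attr(, "report")` tibble (epoch, stage, band, power, threshold,
#'   flagged).
#' @export
detect_artifacts <- function(swa, hf, window = 15, factor_swa = 2,
                             factor_hf = 2.5) {
  if (nrow(swa$power) != nrow(hf$power)) {
    stop_swatopo("swa and hf must cover the same epochs.",
                 "swatopo_parameter_error")
  }
  if (window < 3 || window %% 2 == 0) {
    stop_swatopo("window must be an odd integer >= 3.",
                 "swatopo_parameter_error")
  }
  good <- setdiff(swa$channel_labels, swa$bad_channels)
  gi <- match(good, swa$channel_labels)
  p_swa <- rowMeans(swa$power[, gi, drop = FALSE])
  p_hf <- rowMeans(hf$power[, gi, drop = FALSE])
  n <- length(p_swa)
  is_nrem <- swa$epoch_stage %in% NREM_STAGES
  thr_swa <- thr_hf <- rep(Inf, n)
  for (cls in c(TRUE, FALSE)) {
    idx <- which(is_nrem == cls)
    if (!length(idx)) next
    thr_swa[idx] <- factor_swa * moving_average(p_swa[idx], window)
    thr_hf[idx] <- factor_hf * moving_average(p_hf[idx], window)
  }
  flagged <- p_swa > thr_swa | p_hf > thr_hf
  report <- dplyr::bind_rows(
    tibble(epoch = seq_len(n) - 1L, stage = swa$epoch_stage, band = "swa",
           power = p_swa, threshold = thr_swa, flagged = p_swa > thr_swa),
    tibble(epoch = seq_len(n) - 1L, stage = swa$epoch_stage, band = "hf",
           power = p_hf, threshold = thr_hf, flagged = p_hf > thr_hf)
  )
  attr(flagged, "report") <- report
  flagged
}

#' @rdname detect_artifacts
#' @param mask flag vector from `detect_artifacts()`.
#' @param x an `epoch_band_power` object to receive the mask.
#' @return `set_artifacts()`: `x` with the artifact mask applied.
#' @export
set_artifacts <- function(x, mask) {
  stopifnot(inherits(x, "epoch_band_power"), length(mask) == nrow(x$power))
  x$artifact <- as.logical(mask)
  x
}

#' Topographic map
#'
#' One scalar per electrode: absolute band power (uV^2), relative power
#' (unitless, mean exactly 1 over electrodes) or log-relative power.
#'
#' @param values named numeric vector or tibble with `electrode`, `value`.
#' @param kind `"absolute"`, `"relative"` or `"log_relative"`.
#' @param bd the [band()] the map summarizes.
#' @return a `topomap` tibble (`electrode`, `value`).
#' @export
topomap <- function(values, kind = c("absolute", "relative", "log_relative"),
                    bd = swa_band()) {
  kind <- match.arg(kind)
  if (is.data.frame(values)) {
    df <- as_tibble(values[, c("electrode", "value")])
  } else {
    df <- tibble(electrode = names(values), value = unname(values))
  }
  if (anyDuplicated(df$electrode)) {
    stop_swatopo("duplicate electrode in topomap.", "swatopo_format_error")
  }
  if (kind == "absolute" && any(df$value < 0)) {
    stop_swatopo("absolute maps must be non-negative.",
                 "swatopo_validation_error")
  }
  if (kind == "relative" && abs(mean(df$value) - 1) > 1e-12) {
    stop_swatopo("relative maps must average exactly 1.",
                 "swatopo_validation_error")
  }
  attr(df, "kind") <- kind
  attr(df, "band") <- bd
  class(df) <- c("topomap", class(df))
  df
}

#' @export
print.topomap <- function(x, ...) {
  cat(sprintf("<topomap [%s], %d electrodes, %g-%g Hz>\n", attr(x, "kind"),
              nrow(x), attr(x, "band")$low, attr(x, "band")$high))
  NextMethod()
}

map_kind <- function(map) attr(map, "kind")

#' Whole-night SWA topography
#'
#' Per-channel mean band power over artifact-free epochs of the selected
#' stages (N2 and N3 by default).
#'
#' @param power an `epoch_band_power` object (artifact mask applied).
#' @param stages stages to average over.
#' @param epochs_subset optional 0-based epoch indices to restrict to (used
#'   for per-cycle maps).
#' @return an absolute [topomap()].
#' @export
swa_map <- function(power, stages = c("N2", "N3"), epochs_subset = NULL) {
  stopifnot(inherits(power, "epoch_band_power"))
  keep <- power$epoch_stage %in% stages & !power$artifact
  if (!is.null(epochs_subset)) {
    sel <- rep(FALSE, nrow(power$power))
    sel[epochs_subset + 1L] <- TRUE
    keep <- keep & sel
  }
  if (!any(keep)) {
    stop_swatopo("no artifact-free epochs in the selected stages.",
                 "swatopo_validation_error")
  }
  v <- colMeans(power$power[keep, , drop = FALSE])
  topomap(v, "absolute", power$band)
}

#' Interpolate bad channels on a map
#'
#' Replaces each bad channel's value by the inverse great-circle-distance
#' weighted mean of its `k` nearest good channels (spherical interpolation at
#' the map level; signals themselves are never interpolated). Interpolated
#' values are convex combinations of donor values.
#'
#' @param map a [topomap()].
#' @param mont a [montage()] covering the map electrodes.
#' @param bad electrode labels to interpolate.
#' @param k number of donor neighbours (default 4).
#' @return the map with bad-channel values replaced.
#' @export
interpolate_bad_channels <- function(map, mont, bad, k = 4) {
  if (!length(bad)) return(map)
  good <- setdiff(map$electrode, bad)
  if (length(good) < 3) {
    stop_swatopo("interpolation needs at least three good channels.",
                 "swatopo_validation_error")
  }
  d <- arc_distances(mont)
  vals <- stats::setNames(map$value, map$electrode)
  for (b in bad) {
    db <- d[b, good]
    donors <- names(sort(db))[seq_len(min(k, length(good)))]
    w <- 1 / pmax(d[b, donors], 1e-9)
    vals[b] <- sum(w * vals[donors]) / sum(w)
  }
  out <- map
  out$value <- unname(vals[map$electrode])
  out
}

#' Normalize a map to its mean over electrodes
#'
#' Divides every value by the arithmetic mean over all electrodes, yielding a
#' relative map with mean exactly 1; global (state-dependent) power
#' differences cancel and only the spatial pattern remains.
#'
#' @param map an absolute [topomap()] with positive mean.
#' @return a relative [topomap()].
#' @export
relativize <- function(map) {
  if (map_kind(map) != "absolute") {
    stop_swatopo("relativize expects an absolute map.",
                 "swatopo_parameter_error")
  }
  m <- mean(map$value)
  if (m <= 0) {
    stop_swatopo("map mean must be positive.", "swatopo_validation_error")
  }
  topomap(stats::setNames(map$value / m, map$electrode), "relative",
          attr(map, "band"))
}

#' Log-transform a relative map
#'
#' Natural log, element-wise, to approach normality before correlation
#' analyses. Downstream Pearson correlations are invariant to the log base.
#'
#' @param map a relative [topomap()] with strictly positive values.
#' @return a log-relative [topomap()].
#' @export
log_map <- function(map) {
  if (map_kind(map) != "relative") {
    stop_swatopo("log_map expects a relative map.", "swatopo_parameter_error")
  }
  if (any(map$value <= 0)) {
    stop_swatopo("relative values must be strictly positive.",
                 "swatopo_validation_error")
  }
  topomap(stats::setNames(log(map$value), map$electrode), "log_relative",
          attr(map, "band"))
}

#' Read / write a topographic map TSV
#'
#' Tab-separated `electrode  value` with `#` header lines recording the map
#' kind and band; values are written with 17 significant digits so re-reading
#' reproduces them exactly.
#'
#' @param map a [topomap()].
#' @param path file path.
#' @return `write_topomap()` the path invisibly; `read_topomap()` the map.
#' @export
write_topomap <- function(map, path) {
  hdr <- c(sprintf("# kind: %s", map_kind(map)),
           sprintf("# band: %s %s", fmt17(attr(map, "band")$low),
                   fmt17(attr(map, "band")$high)),
           "electrode\tvalue")
  writeLines(c(hdr, sprintf("%s\t%s", map$electrode, fmt17(map$value))), path)
  invisible(path)
}

#' @rdname write_topomap
#' @export
read_topomap <- function(path) {
  if (!file.exists(path)) {
    stop_swatopo(sprintf("topomap file not found: %s", path),
                 "swatopo_io_error")
  }
  lines <- readLines(path)
  kind <- sub("^# kind: ", "", lines[1])
  bd <- as.numeric(strsplit(sub("^# band: ", "", lines[2]), " ")[[1]])
  rows <- strsplit(lines[-(1:3)], "\t")
  topomap(
    tibble(electrode = vapply(rows, `[`, "", 1),
           value = as.numeric(vapply(rows, `[`, "", 2))),
    kind, band(bd[1], bd[2])
  )
}
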