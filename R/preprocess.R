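# FFT-based convolution of each row of x with kernel h, returning the
# central (zero-phase) part; edges are reflection-padded to tame transients.
fir_apply <- function(x, h) {
  L <- length(h)
  half <- (L - 1) / 2
  nt <- ncol(x)
  if (half >= nt) {
    stop_swatopo("recording too short for the designed filter.",
                 "swatopo_parameter_error")
  }
  padl <- x[, (half + 1):2, drop = FALSE]
  padr <- x[, (nt - 1):(nt - half), drop = FALSE]
  xp <- cbind(padl, x, padr)
  np <- ncol(xp)
  nfft <- stats::nextn(np + L - 1, 2)
  H <- fft(c(h, rep(0, nfft - L)))
  out <- matrix(0, nrow(x), nt)
  # batch channels through mvfft to amortize allocation overhead
  chunk <- max(1L, min(nrow(x), as.integer(2^26 / nfft)))
  for (i0 in seq(1, nrow(x), by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, nrow(x))
    Xp <- matrix(0, nfft, length(ii))
    Xp[seq_len(np), ] <- t(xp[ii, , drop = FALSE])
    Y <- stats::mvfft(stats::mvfft(Xp) * H, inverse = TRUE)
    # kernel delay half + left pad half => signal starts at 2*half + 1
    out[ii, ] <- t(Re(Y[(2 * half + 1):(2 * half + nt), , drop = FALSE])) / nfft
  }
  out
}

#' Zero-phase band-pass filter
#'
#' Hamming-windowed linear-phase FIR band-pass applied channel-wise with
#' group-delay compensation, so slow waves are not phase-shifted. The filter
#' order is set by the narrower transition band (0.5 Hz at the low edge,
#' 2 Hz at the high edge by default). Signal length is preserved; edges are
#' reflection-padded during convolution.
#'
#' @param rec a [raw_recording()].
#' @param low,high band edges in Hz, `0 < low < high < sampling_rate / 2`.
#' @param trans_low,trans_high transition widths in Hz.
#' @return the filtered [raw_recording()].
#' @export
bandpass_filter <- function(rec, low = 0.5, high = 40,
                            trans_low = 0.5, trans_high = 2) {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$sampling_rate
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop_swatopo("need 0 < low < high < sampling_rate / 2.",
                 "swatopo_parameter_error")
  }
  width <- min(trans_low, trans_high)
  n <- ceiling(3.3 * fs / width)
  if (n %% 2 == 1) n <- n + 1            # even order -> odd length, type I
  h <- signal::fir1(n, c(low, high) / (fs / 2), type = "pass")
  out <- rec
  out$samples <- fir_apply(rec$samples, h)
  rownames(out$samples) <- rec$channel_labels
  out
}

#' Re-reference to the average of good channels
#'
#' Subtracts, at every sample, the instantaneous mean over good channels from
#' each good channel. Bad channels pass through unchanged and stay flagged;
#' after the transform the mean over good channels is zero at every sample.
#'
#' @param rec a [raw_recording()] with at least two good channels.
#' @return the re-referenced [raw_recording()] with
#'   `reference = "average_of_good"`.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "raw_recording"))
  good <- good_channels(rec)
  if (length(good) < 2) {
    stop_swatopo("average reference needs at least two good channels.",
                 "swatopo_parameter_error")
  }
  gi <- match(good, rec$channel_labels)
  avg <- colMeans(rec$samples[gi, , drop = FALSE])
  out <- rec
  out$samples[gi, ] <- sweep(rec$samples[gi, , drop = FALSE], 2, avg)
  out$reference <- "average_of_good"
  out
}

#' Cut a recording into hypnogram-aligned epochs
#'
#' Contiguous non-overlapping epochs of `hyp$epoch_length` seconds starting
#' at the first sample (the recording is assumed to start at lights-off).
#' Each epoch is tagged with its scored stage; a trailing partial epoch is
#' discarded.
#'
#' @param rec a [raw_recording()].
#' @param hyp a [hypnogram()]; the recording must span its full length.
#' @return an [epoched_recording()].
#' @export
epoch_by_hypnogram <- function(rec, hyp) {
  stopifnot(inherits(rec, "raw_recording"), inherits(hyp, "hypnogram"))
  spe <- hyp$epoch_length * rec$sampling_rate
  if (abs(spe - round(spe)) > 1e-9) {
    stop_swatopo("epoch_length x sampling_rate must be an integer.",
                 "swatopo_parameter_error")
  }
  spe <- as.integer(round(spe))
  n_ep <- length(hyp$stages)
  need <- n_ep * spe
  if (ncol(rec$samples) < need) {
    stop_swatopo(
      sprintf("recording too short for hypnogram: %d samples short.",
              need - ncol(rec$samples)),
      "swatopo_validation_error"
    )
  }
  nch <- nrow(rec$samples)
  ep <- array(0, dim = c(n_ep, nch, spe))
  for (e in seq_len(n_ep)) {
    ep[e, , ] <- rec$samples[, ((e - 1) * spe + 1):(e * spe)]
  }
  epoched_recording(ep, hyp$stages, rec$channel_labels, rec$sampling_rate,
                    rec$bad_channels)
}
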