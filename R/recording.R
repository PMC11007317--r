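#' Raw multichannel recording
#'
#' Container for a continuous EEG recording: a channels-by-samples matrix of
#' potentials in microvolts plus channel labels, the sampling rate and a set
#' of bad-channel flags. `reference` records whether the data are still at
#' the recording reference or have been re-referenced to the average of the
#' good channels.
#'
#' @param samples numeric matrix, channels x timepoints, microvolts.
#' @param channel_labels character vector, one unique label per row.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param bad_channels character vector, subset of `channel_labels`.
#' @param reference `"recording_reference"` or `"average_of_good"`.
#' @return a `raw_recording` object.
#' @export
raw_recording <- function(samples, channel_labels, sampling_rate,
                          bad_channels = character(),
                          reference = c("recording_reference", "average_of_good")) {
  reference <- match.arg(reference)
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) {
    stop_swatopo("samples must be numeric.", "swatopo_format_error")
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(samples)) {
    stop_swatopo("one channel label per sample row is required.",
                 "swatopo_format_error")
  }
  if (anyDuplicated(channel_labels)) {
    stop_swatopo("channel labels must be unique.", "swatopo_format_error")
  }
  assert_scalar_number(sampling_rate, "sampling_rate")
  if (sampling_rate <= 0) {
    stop_swatopo("sampling_rate must be positive.", "swatopo_parameter_error")
  }
  bad_channels <- as.character(bad_channels)
  if (!all(bad_channels %in% channel_labels)) {
    stop_swatopo("bad_channels must be a subset of channel_labels.",
                 "swatopo_format_error")
  }
  rownames(samples) <- channel_labels
  structure(
    list(
      samples = samples,
      channel_labels = channel_labels,
      sampling_rate = sampling_rate,
      bad_channels = bad_channels,
      reference = reference
    ),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf(
    "<raw_recording: %d channels x %d samples @ %g Hz (%.1f s), %d bad, ref=%s>\n",
    nrow(x$samples), ncol(x$samples), x$sampling_rate,
    ncol(x$samples) / x$sampling_rate, length(x$bad_channels), x$reference
  ))
  invisible(x)
}

good_channels <- function(rec) setdiff(rec$channel_labels, rec$bad_channels)

n_samples <- function(rec) ncol(rec$samples)

#' Hypnogram-aligned epoched recording
#'
#' Epochs of fixed length cut from a recording starting at lights-off, each
#' tagged with its visually scored sleep stage.
#'
#' @param epochs numeric array, epoch x channel x sample, microvolts (or
#'   microvolts per mm^2 after a Laplacian transform).
#' @param epoch_stage character vector of stages, one per epoch.
#' @param channel_labels,sampling_rate,bad_channels as in [raw_recording()].
#' @param units signal units, `"uV"` or `"uV/mm^2"`.
#' @return an `epoched_recording` object.
#' @export
epoched_recording <- function(epochs, epoch_stage, channel_labels,
                              sampling_rate, bad_channels = character(),
                              units = "uV") {
  if (length(dim(epochs)) != 3L) {
    stop_swatopo("epochs must be an epoch x channel x sample array.",
                 "swatopo_format_error")
  }
  if (dim(epochs)[1] != length(epoch_stage)) {
    stop_swatopo("one stage per epoch is required.", "swatopo_format_error")
  }
  if (dim(epochs)[2] != length(channel_labels)) {
    stop_swatopo("channel count mismatch.", "swatopo_format_error")
  }
  if (!all(epoch_stage %in% STAGES)) {
    stop_swatopo("unknown stage label in epoch_stage.", "swatopo_format_error")
  }
  structure(
    list(
      epochs = epochs,
      epoch_stage = as.character(epoch_stage),
      channel_labels = as.character(channel_labels),
      sampling_rate = sampling_rate,
      bad_channels = as.character(bad_channels),
      units = units
    ),
    class = "epoched_recording"
  )
}

#' @export
print.epoched_recording <- function(x, ...) {
  cat(sprintf("<epoched_recording: %d epochs x %d channels x %d samples @ %g Hz [%s]>\n",
              dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3],
              x$sampling_rate, x$units))
  invisible(x)
}
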