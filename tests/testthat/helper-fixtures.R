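# shared fixtures, all generated in code

# 12-electrode right-hemisphere subset of the standard montage containing the
# default planted cluster; keeps tests fast while preserving real geometry
mini_montage <- function() {
  m <- standard_montage_59()
  keep <- c("C6", "CP4", "CP6", "FT8", "P4", "P6",
            "C4", "CP2", "P2", "T8", "TP8", "P8")
  montage(m[match(keep, m$label), ], head_radius = head_radius(m))
}

# full-sphere Fibonacci montage: well-posed spherical-spline interpolation
# everywhere, used for operator-level CSD checks
fib_montage <- function(n = 100, r = 85) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  montage(
    tibble::tibble(label = sprintf("E%03d", seq_len(n)),
                   x = r * sin(phi) * cos(theta),
                   y = r * sin(phi) * sin(theta),
                   z = r * cos(phi)),
    head_radius = r
  )
}

# toy two-channel recording of pure sinusoids
sine_recording <- function(freqs, fs = 500, dur = 20, amps = NULL) {
  t <- (0:(dur * fs - 1)) / fs
  amps <- amps %||% rep(1, length(freqs))
  x <- do.call(rbind, lapply(seq_along(freqs),
                             function(i) amps[i] * sin(2 * pi * freqs[i] * t)))
  raw_recording(x, sprintf("ch%d", seq_along(freqs)), fs)
}

# epoch_band_power object built directly from a power matrix
fake_band_power <- function(power, stages, bad = character(), bd = swa_band()) {
  colnames(power) <- colnames(power) %||% sprintf("e%d", seq_len(ncol(power)))
  structure(
    list(power = power, band = bd, epoch_stage = stages,
         artifact = rep(FALSE, nrow(power)),
         channel_labels = colnames(power), bad_channels = bad),
    class = "epoch_band_power"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
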