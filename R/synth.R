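#' Synthetic study configuration
#'
#' Parameters of the synthetic-data generator, which emulates the statistical
#' structure of a 54-subject, 59-electrode home-sleep study: N2/N3-dominated
#' hypnograms with 4-5 NREM-REM cycles, 1/f background EEG with
#' stage-dependent slow oscillations, spatially smooth log-relative SWA
#' topographies with a planted right-posterior cluster whose mean correlates
#' with a contribution-minus-belief prosociality score at `effect_rho`.
#'
#' @param n_subjects number of subjects (default 54).
#' @param mont electrode [montage()] (default built-in 59-channel).
#' @param planted_cluster electrode labels carrying the planted association
#'   (default the six right temporoparietal sites C6, CP4, CP6, FT8, P4, P6).
#' @param effect_rho population correlation between the planted-cluster mean
#'   log-relative SWA and the behavioral score (default 0.49; |rho| < 1).
#' @param cluster_gain standard deviation of the subject-level latent factor
#'   loading on the planted cluster, in units of the field sd (default 2,
#'   making planted electrodes individually suprathreshold in most samples).
#' @param spatial_smoothness length scale (mm) of the squared-exponential
#'   spatial correlation of the topography field (default 40).
#' @param map_log_sd standard deviation of the log-relative maps (default
#'   0.25, giving relative SWA spanning roughly 50-180% of the electrode
#'   mean).
#' @param n_cycles target number of NREM-REM sleep cycles (default 4).
#' @param stage_fractions named fractions of sleep time per stage (defaults
#'   N1 8%, N2 46%, N3 25%, REM 21%).
#' @param sampling_rate Hz for raw-signal generation (default 500).
#' @param one_over_f_alpha spectral slope of the background noise (default 1).
#' @param swa_amplitude_n2,swa_amplitude_n3 slow-oscillation amplitude (uV)
#'   during N2/N3 at unit channel gain (defaults 40 and 80; N3 > N2).
#' @param noise_amplitude background noise RMS in uV (default 15).
#' @param artifact_rate fraction of epochs receiving an injected high-power
#'   artifact (default 0.02).
#' @param score_mean,score_sd target mean and sd of the integer
#'   contribution-minus-belief score (defaults 1.56 and 4.03).
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_subjects = 54,
                         mont = standard_montage_59(),
                         planted_cluster = c("C6", "CP4", "CP6", "FT8",
                                             "P4", "P6"),
                         effect_rho = 0.49,
                         cluster_gain = 2,
                         spatial_smoothness = 40,
                         map_log_sd = 0.25,
                         n_cycles = 4,
                         stage_fractions = c(N1 = 0.08, N2 = 0.46,
                                             N3 = 0.25, REM = 0.21),
                         sampling_rate = 500,
                         one_over_f_alpha = 1,
                         swa_amplitude_n2 = 40,
                         swa_amplitude_n3 = 80,
                         noise_amplitude = 15,
                         artifact_rate = 0.02,
                         score_mean = 1.56,
                         score_sd = 4.03) {
  if (abs(effect_rho) >= 1) {
    stop_swatopo("|effect_rho| must be < 1.", "swatopo_parameter_error")
  }
  if (!all(planted_cluster %in% mont$label)) {
    stop_swatopo("planted_cluster must be a subset of montage labels.",
                 "swatopo_parameter_error")
  }
  if (sum(stage_fractions) > 1 + 1e-9 || any(stage_fractions < 0)) {
    stop_swatopo("stage fractions must be non-negative and sum to <= 1.",
                 "swatopo_parameter_error")
  }
  structure(
    list(n_subjects = n_subjects, mont = mont,
         planted_cluster = planted_cluster, effect_rho = effect_rho,
         cluster_gain = cluster_gain,
         spatial_smoothness = spatial_smoothness, map_log_sd = map_log_sd,
         n_cycles = n_cycles, stage_fractions = stage_fractions,
         sampling_rate = sampling_rate, one_over_f_alpha = one_over_f_alpha,
         swa_amplitude_n2 = swa_amplitude_n2,
         swa_amplitude_n3 = swa_amplitude_n3,
         noise_amplitude = noise_amplitude, artifact_rate = artifact_rate,
         score_mean = score_mean, score_sd = score_sd),
    class = "synth_config"
  )
}

#' Generate a synthetic hypnogram
#'
#' Builds `n_cycles` NREM-REM cycles: a short N1 entry, N2 and N3 blocks
#' (N3 shrinking and REM growing across the night, as in real sleep), a REM
#' period per cycle, brief awakenings between cycles, and a few wake epochs
#' before sleep onset and after the final awakening. Block lengths are
#' jittered around targets derived from `stage_fractions`.
#'
#' @param cfg a [synth_config()].
#' @param seed integer seed.
#' @param total_sleep_min target total sleep time in minutes (default 430).
#' @return a [hypnogram()] of 30-s epochs.
#' @export
generate_hypnogram <- function(cfg = synth_config(), seed = 1L,
                               total_sleep_min = 430) {
  set.seed(seed)
  k <- cfg$n_cycles
  tot <- total_sleep_min * 2                    # epochs of sleep
  per_cycle <- tot / k
  fr <- cfg$stage_fractions
  jit <- function(n, frac = 0.15) {
    max(1L, as.integer(round(n * (1 + runif(1, -frac, frac)))))
  }
  stages <- rep("W", 4 + sample(0:4, 1))        # sleep-onset latency
  for (i in seq_len(k)) {
    # N3 declines across the night, REM grows
    w_n3 <- 2 * (k - i + 1) / (k + 1)
    w_rem <- 2 * i / (k + 1)
    n1 <- jit(per_cycle * fr[["N1"]])
    n3 <- jit(per_cycle * fr[["N3"]] * w_n3)
    if (fr[["REM"]] > 0) {
      rem <- jit(per_cycle * fr[["REM"]] * w_rem)
      if (i == 1) rem <- max(4L, as.integer(round(rem / 2)))  # short first REM
      if (i > 1) rem <- max(rem, 10L)           # meets the 5-min REM minimum
    } else {
      rem <- 0L
    }
    n2 <- jit(per_cycle - n1 - n3 - rem)
    n2a <- n2 %/% 2
    stages <- c(stages,
                rep("N1", n1), rep("N2", n2a), rep("N3", n3),
                rep("N2", n2 - n2a), rep("REM", rem))
    if (i < k && runif(1) < 0.6) stages <- c(stages, rep("W", sample(1:2, 1)))
  }
  stages <- c(stages, rep("W", 2 + sample(0:2, 1)))
  hypnogram(stages)
}

# squared-exponential spatial covariance over montage electrodes
spatial_covariance <- function(mont, length_scale) {
  d <- arc_distances(mont)
  exp(-(d / length_scale)^2)
}

#' Generate a subjects-by-electrodes topography dataset
#'
#' Fast path feeding the cluster statistics directly: per subject, a
#' spatially correlated Gaussian field on the montage (squared-exponential
#' correlation with length scale `spatial_smoothness`) plus a subject-level
#' latent factor loading only on the planted cluster; scores are built from
#' the planted-cluster mean so that the population correlation equals
#' `effect_rho` (`effect_rho = 0` yields null data). Each subject's map is
#' exponentiated, renormalized to electrode-mean 1 and re-logged, so every
#' relative map has mean exactly 1 before the log.
#'
#' @param cfg a [synth_config()].
#' @param seed integer seed.
#' @return a [swa_dataset()] with `attr(,"latent_scores")` holding the
#'   continuous (pre-rounding) scores.
#' @export
generate_topography_dataset <- function(cfg = synth_config(), seed = 1L) {
  set.seed(seed)
  mont <- cfg$mont
  E <- nrow(mont)
  n <- cfg$n_subjects
  K <- spatial_covariance(mont, cfg$spatial_smoothness)
  Lc <- chol(K + diag(1e-9, E))
  field <- matrix(rnorm(n * E), n, E) %*% Lc     # n x E, unit variance
  u <- rnorm(n)                                   # latent cluster factor
  ci <- match(cfg$planted_cluster, mont$label)
  raw <- field
  raw[, ci] <- raw[, ci] + cfg$cluster_gain * u
  maps <- raw * cfg$map_log_sd
  # renormalize: relative map mean exactly 1 before log
  rel <- exp(maps)
  rel <- rel / rowMeans(rel)
  maps <- log(rel)
  colnames(maps) <- mont$label
  # score from the realized (renormalized) cluster mean, so the target
  # correlation refers to the quantity the analysis actually uses
  cm <- rowMeans(maps[, ci, drop = FALSE])
  rho <- cfg$effect_rho
  z <- if (n > 1) as.numeric(scale(cm)) else 0   # undefined for one subject
  latent <- rho * z + sqrt(1 - rho^2) * rnorm(n)
  ds <- swa_dataset(maps, latent, mont = mont)
  attr(ds, "latent_scores") <- latent
  ds
}

# 1/f^alpha noise via spectral shaping, n samples at rate fs, unit RMS
one_over_f_noise <- function(n, fs, alpha) {
  nf <- n %/% 2 + 1
  f <- (0:(nf - 1)) * fs / n
  amp <- c(0, 1 / f[-1]^(alpha / 2))
  ph <- runif(nf, 0, 2 * pi)
  spec <- amp * exp(1i * ph)
  full <- c(spec, Conj(rev(spec[2:(n - nf + 1)])))
  x <- Re(fft(full, inverse = TRUE))
  x / sd(x)
}

#' Generate a raw synthetic recording for one subject
#'
#' Slow path exercising the full signal chain: per channel, 1/f background
#' noise plus, during N2 and N3 epochs, a band-limited 0.8-2 Hz slow
#' oscillation whose amplitude is the stage factor (N3 > N2) times that
#' channel's `subject_gain`. A configurable fraction of epochs receives an
#' injected broadband high-power artifact so the artifact screening has
#' something to find.
#'
#' @param hyp a [hypnogram()].
#' @param cfg a [synth_config()].
#' @param subject_gain named per-channel amplitude gain (default 1
#'   everywhere); SWA power scales with its square.
#' @param seed integer seed.
#' @param channels channel labels to generate (default the full montage).
#' @return a [raw_recording()] spanning exactly the hypnogram.
#' @export
generate_raw_recording <- function(hyp, cfg = synth_config(),
                                   subject_gain = NULL, seed = 1L,
                                   channels = cfg$mont$label) {
  set.seed(seed)
  fs <- cfg$sampling_rate
  spe <- as.integer(hyp$epoch_length * fs)
  n_ep <- length(hyp$stages)
  nt <- n_ep * spe
  nch <- length(channels)
  if (is.null(subject_gain)) {
    subject_gain <- stats::setNames(rep(1, nch), channels)
  }
  tt <- (0:(spe - 1)) / fs
  artifact_epochs <- which(runif(n_ep) < cfg$artifact_rate)
  x <- matrix(0, nch, nt)
  for (ch in seq_len(nch)) {
    bg <- cfg$noise_amplitude * one_over_f_noise(nt, fs, cfg$one_over_f_alpha)
    x[ch, ] <- bg
  }
  for (e in seq_len(n_ep)) {
    st <- hyp$stages[e]
    sl <- ((e - 1) * spe + 1):(e * spe)
    if (st %in% c("N2", "N3")) {
      amp0 <- if (st == "N3") cfg$swa_amplitude_n3 else cfg$swa_amplitude_n2
      # band-limited 0.8-2 Hz oscillation, random frequency and phase per
      # epoch, shared across channels (slow waves are global events)
      f0 <- runif(1, 0.8, 2)
      ph <- runif(1, 0, 2 * pi)
      wave <- sin(2 * pi * f0 * tt + ph)
      for (ch in seq_len(nch)) {
        x[ch, sl] <- x[ch, sl] + amp0 * subject_gain[[channels[ch]]] * wave
      }
    }
    if (e %in% artifact_epochs) {
      x[, sl] <- x[, sl] + matrix(rnorm(nch * spe, sd = 8 * cfg$noise_amplitude),
                                  nch, spe)
    }
  }
  raw_recording(x, channels, fs)
}

#' Generate behavioral records correlated with cluster-mean SWA
#'
#' Latent score `rho * standardized cluster mean + sqrt(1 - rho^2) * noise`,
#' affinely mapped to the target score mean/sd, rounded to integer points and
#' realized as a contribution/belief pair within `[0, 20]`. Rounding and
#' clipping attenuate the realized correlation slightly; the continuous
#' latent score is returned alongside for reference.
#'
#' @param cluster_means numeric per-subject planted-cluster mean SWA.
#' @param cfg a [synth_config()].
#' @param seed integer seed.
#' @return behavioral tibble: `subject_id`, `contribution`, `belief`,
#'   `score`, `latent`.
#' @export
generate_behavior <- function(cluster_means, cfg = synth_config(),
                              seed = 1L) {
  set.seed(seed)
  n <- length(cluster_means)
  rho <- cfg$effect_rho
  z <- if (n > 1) as.numeric(scale(cluster_means)) else 0
  latent <- rho * z + sqrt(1 - rho^2) * rnorm(n)
  target <- latent * cfg$score_sd + cfg$score_mean
  score <- pmin(20, pmax(-20, round(target)))
  belief <- pmin(20 - pmax(score, 0), pmax(0 - pmin(score, 0),
                                           round(rnorm(n, 10, 3))))
  belief <- pmin(20, pmax(0, belief))
  contribution <- belief + score
  # clip and keep score = contribution - belief exact
  contribution <- pmin(20, pmax(0, contribution))
  score <- contribution - belief
  tibble(
    subject_id = sprintf("s%02d", seq_len(n)),
    contribution = as.integer(contribution),
    belief = as.integer(belief),
    score = as.integer(score),
    latent = latent
  )
}
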