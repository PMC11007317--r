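#' Sleep parameters from a hypnogram
#'
#' Computes the standard polysomnography summary over the in-bed portion of
#' the hypnogram: total sleep time (TST, minutes of non-wake epochs), sleep
#' efficiency (TST as a percentage of time in bed), wake after sleep onset
#' (wake minutes between the first and last sleep epoch; terminal wake is
#' excluded) and the percentage of TST spent in each stage.
#'
#' @param hyp a [hypnogram()] with at least one sleep epoch in bed.
#' @return one-row tibble: `total_sleep_time_min`, `time_in_bed_min`,
#'   `sleep_efficiency_pct`, `sleep_onset_latency_min`, `waso_min`,
#'   `n1_pct`, `n2_pct`, `n3_pct`, `rem_pct`.
#' @export
sleep_parameters <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  st <- in_bed_stages(hyp)
  mins <- hyp$epoch_length / 60
  sleep <- st != "W"
  if (!any(sleep)) {
    stop_swatopo("hypnogram contains no sleep within time in bed.",
                 "swatopo_validation_error")
  }
  onset <- which(sleep)[1]
  last_sleep <- max(which(sleep))
  tst <- sum(sleep) * mins
  tib <- length(st) * mins
  waso <- if (last_sleep > onset) {
    sum(st[onset:last_sleep] == "W") * mins
  } else 0
  pct <- function(stage) 100 * sum(st == stage) / sum(sleep)
  tibble(
    total_sleep_time_min = tst,
    time_in_bed_min = tib,
    sleep_efficiency_pct = 100 * tst / tib,
    sleep_onset_latency_min = (onset - 1) * mins,
    waso_min = waso,
    n1_pct = pct("N1"),
    n2_pct = pct("N2"),
    n3_pct = pct("N3"),
    rem_pct = pct("REM")
  )
}

#' Segment a hypnogram into NREM-REM sleep cycles
#'
#' Feinberg & Floyd style criteria: a cycle is a maximal NREM period of at
#' least `nrem_min_min` minutes of sleep containing N2/N3, followed by a REM
#' period of at least `rem_min_min` minutes (the REM minimum is waived for
#' the first cycle). A REM run shorter than the minimum does not close the
#' cycle and is merged forward. A trailing NREM period without subsequent REM
#' forms a final cycle (with an empty REM part) when it meets the NREM
#' minimum and contains N2/N3.
#'
#' @param hyp a [hypnogram()] containing N2 or N3 sleep.
#' @param nrem_min_min minimum NREM-period sleep duration, minutes (15).
#' @param rem_min_min minimum REM-period duration, minutes (5).
#' @return tibble with one row per cycle: `cycle`, `nrem_start`, `nrem_end`,
#'   `rem_start`, `rem_end` (0-based epoch indices into the full hypnogram,
#'   half-open; `rem_start == rem_end` for an empty REM part).
#' @export
segment_cycles <- function(hyp, nrem_min_min = 15, rem_min_min = 5) {
  stopifnot(inherits(hyp, "hypnogram"))
  st <- hyp$stages
  if (!any(st %in% c("N2", "N3"))) {
    stop_swatopo("hypnogram contains no N2/N3 sleep.",
                 "swatopo_validation_error")
  }
  epm <- 60 / hyp$epoch_length               # epochs per minute
  nrem_min <- nrem_min_min * epm
  rem_min <- rem_min_min * epm
  sleep_idx <- which(st != "W" & seq_along(st) > hyp$lights_off &
                     seq_along(st) <= hyp$wake_up)
  if (!length(sleep_idx)) {
    stop_swatopo("no sleep within time in bed.", "swatopo_validation_error")
  }
  last_sleep <- max(sleep_idx)
  # REM runs as (start, end] 1-based inclusive runs
  r <- rle(st == "REM")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  rem_runs <- tibble(start = starts[r$values], end = ends[r$values],
                     len = r$lengths[r$values])

  cycles <- list()
  cyc_start <- sleep_idx[1]
  n_cycle <- 0L
  repeat {
    cand <- rem_runs[rem_runs$start > cyc_start, , drop = FALSE]
    closed <- FALSE
    for (j in seq_len(nrow(cand))) {
      run <- cand[j, ]
      qualifies <- (n_cycle == 0L) || (run$len >= rem_min)
      nrem_part <- st[cyc_start:(run$start - 1)]
      enough_nrem <- sum(nrem_part != "W" & nrem_part != "REM") >= nrem_min &&
        any(nrem_part %in% c("N2", "N3"))
      if (qualifies && enough_nrem) {
        n_cycle <- n_cycle + 1L
        cycles[[n_cycle]] <- c(nrem_start = cyc_start - 1L,
                               nrem_end = run$start - 1L,
                               rem_start = run$start - 1L,
                               rem_end = run$end)
        nxt <- which(st != "W" & seq_along(st) > run$end &
                     seq_along(st) <= last_sleep)
        if (!length(nxt)) {
          closed <- TRUE
          cyc_start <- NA
          break
        }
        cyc_start <- nxt[1]
        closed <- TRUE
        break
      }
    }
    if (!closed) break
    if (is.na(cyc_start)) break
  }
  # trailing NREM without a qualifying REM period
  if (!is.na(cyc_start)) {
    tail_part <- st[cyc_start:last_sleep]
    if (sum(tail_part != "W" & tail_part != "REM") >= nrem_min &&
        any(tail_part %in% c("N2", "N3"))) {
      n_cycle <- n_cycle + 1L
      cycles[[n_cycle]] <- c(nrem_start = cyc_start - 1L,
                             nrem_end = last_sleep,
                             rem_start = last_sleep, rem_end = last_sleep)
    }
  }
  if (!length(cycles)) {
    stop_swatopo("no sleep cycle satisfies the duration criteria.",
                 "swatopo_validation_error")
  }
  out <- as_tibble(do.call(rbind, cycles))
  out$cycle <- seq_len(nrow(out))
  relocate(out, "cycle")
}

# 0-based epoch indices covered by a cycle's NREM+REM span
cycle_epochs <- function(cycles, i) {
  row <- cycles[cycles$cycle == i, ]
  seq(row$nrem_start, max(row$rem_end, row$nrem_end) - 1L)
}

#' Per-cycle log-relative SWA maps
#'
#' For each requested cycle, averages artifact-free N2/N3 band power over the
#' cycle's epochs, normalizes to the mean over electrodes within that cycle,
#' and log-transforms.
#'
#' @param power an `epoch_band_power` object (whole night, artifact mask
#'   applied).
#' @param cycles cycle table from [segment_cycles()].
#' @param which_cycles cycle numbers (default all).
#' @return named list of log-relative [topomap()]s (`"cycle_1"`, ...).
#' @export
per_cycle_relative_swa <- function(power, cycles,
                                   which_cycles = cycles$cycle) {
  out <- list()
  for (i in which_cycles) {
    ep <- cycle_epochs(cycles, i)
    m <- tryCatch(
      swa_map(power, epochs_subset = ep),
      swatopo_validation_error = function(e) {
        stop_swatopo(
          sprintf("cycle %d has no artifact-free N2/N3 epochs.", i),
          "swatopo_validation_error"
        )
      }
    )
    out[[sprintf("cycle_%d", i)]] <- log_map(relativize(m))
  }
  out
}
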