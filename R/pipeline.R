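#' Analysis configuration
#'
#' Aggregates the pipeline's fixed constants: the SWA band (0.8-4.6 Hz), the
#' artifact screening band (20-40 Hz), 30-s epochs cut into 5-s subepochs,
#' a 0.5-40 Hz band-pass, electrode-level two-sided alpha 0.05, the 95th
#' percentile of the permutation max-cluster-size null as critical cluster
#' threshold, 5000 permutations, a 40-mm adjacency threshold, the artifact
#' moving-average factors/window and the CSD spline constants.
#'
#' @param ... overrides of the defaults listed above (see source for keys).
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    swa_band_low = 0.8, swa_band_high = 4.6,
    artifact_band_low = 20, artifact_band_high = 40,
    epoch_length = 30, subepoch_length = 5,
    filter_low = 0.5, filter_high = 40,
    alpha_electrode = 0.05, cluster_percentile = 95,
    n_permutations = 5000,
    adjacency_mm = 40,
    artifact_factor_swa = 2, artifact_factor_hf = 2.5, artifact_window = 15,
    csd_m = 4, csd_lambda = 1e-5, csd_legendre_terms = 50,
    stages = c("N2", "N3"),
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop_swatopo(sprintf("unknown config key(s): %s",
                         paste(unknown, collapse = ", ")),
                 "swatopo_parameter_error")
  }
  cfg[names(dots)] <- dots
  if (!(cfg$cluster_percentile > 0 && cfg$cluster_percentile < 100)) {
    stop_swatopo("cluster_percentile must lie in (0, 100).",
                 "swatopo_parameter_error")
  }
  structure(cfg, class = "analysis_config")
}

#' Read / write an analysis configuration as YAML
#'
#' Flat keys mirroring [analysis_config()].
#'
#' @param path YAML file path.
#' @return `read_analysis_config()` an `analysis_config`;
#'   `write_analysis_config()` the path, invisibly.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}

#' @rdname read_analysis_config
#' @param cfg an [analysis_config()].
#' @export
write_analysis_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Simulate a per-subject fixture tree
#'
#' Writes, for each synthetic subject, an EDF recording, a hypnogram text
#' file and its share of a common behavior TSV, plus the montage and a JSON
#' manifest recording every seed. Per-channel SWA gains are derived from the
#' same topography model used by [generate_topography_dataset()], so the raw
#' signal chain reproduces the planted cluster-score association.
#'
#' @param synth a [synth_config()]; for tractable file sizes, prefer a
#'   reduced `sampling_rate` and short hypnograms via `total_sleep_min`.
#' @param out_dir output directory (created).
#' @param seed master integer seed.
#' @param total_sleep_min per-subject sleep duration target in minutes.
#' @return the manifest list, invisibly.
#' @export
run_simulate <- function(synth = synth_config(), out_dir, seed = 1L,
                         total_sleep_min = 430) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- generate_topography_dataset(synth, seed = seed)
  # per-channel amplitude gains: exp of half the log map so power tracks map
  gains <- exp(ds$maps / 2)
  ci <- match(synth$planted_cluster, ds$electrodes)
  beh <- generate_behavior(rowMeans(ds$maps[, ci, drop = FALSE]), synth,
                           seed = seed + 1L)
  write_behavior(beh[, c("subject_id", "contribution", "belief", "score")],
                 file.path(out_dir, "behavior.tsv"))
  write_montage(synth$mont, file.path(out_dir, "montage.tsv"))
  manifest <- list(seed = seed, n_subjects = synth$n_subjects,
                   sampling_rate = synth$sampling_rate, subjects = list())
  for (i in seq_len(synth$n_subjects)) {
    sid <- beh$subject_id[i]
    sdir <- file.path(out_dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    hseed <- seed + 100L + i
    rseed <- seed + 10000L + i
    hyp <- generate_hypnogram(synth, seed = hseed,
                              total_sleep_min = total_sleep_min)
    rec <- generate_raw_recording(hyp, synth,
                                  subject_gain = stats::setNames(
                                    gains[i, ], ds$electrodes),
                                  seed = rseed)
    write_edf(rec, file.path(sdir, "recording.edf"))
    write_hypnogram(hyp, file.path(sdir, "hypnogram.txt"))
    manifest$subjects[[sid]] <- list(hypnogram_seed = hseed,
                                     recording_seed = rseed)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# whole pipeline for one subject: raw recording -> log-relative SWA map
# (plus per-cycle maps); returns a list of maps and the sleep parameters
analyze_subject <- function(rec, hyp, mont, cfg = analysis_config(),
                            csd = FALSE) {
  rec <- bandpass_filter(rec, cfg$filter_low, cfg$filter_high)
  rec <- rereference_average(rec)
  ep <- epoch_by_hypnogram(rec, hyp)
  swa_bd <- band(cfg$swa_band_low, cfg$swa_band_high)
  hf_bd <- band(cfg$artifact_band_low, cfg$artifact_band_high)
  pw_swa <- epoch_band_power(ep, swa_bd, cfg$subepoch_length)
  pw_hf <- epoch_band_power(ep, hf_bd, cfg$subepoch_length)
  mask <- detect_artifacts(pw_swa, pw_hf, cfg$artifact_window,
                           cfg$artifact_factor_swa, cfg$artifact_factor_hf)
  pw_swa <- set_artifacts(pw_swa, mask)
  m <- swa_map(pw_swa, cfg$stages)
  if (length(rec$bad_channels)) {
    m <- interpolate_bad_channels(m, mont, rec$bad_channels)
  }
  night_map <- log_map(relativize(m))
  cycles <- segment_cycles(hyp)
  cyc_maps <- per_cycle_relative_swa(pw_swa, cycles)
  out <- list(night = night_map, cycles = cyc_maps,
              sleep = sleep_parameters(hyp),
              artifact_report = attr(mask, "report"))
  if (csd) {
    out$csd <- csd_swa_pipeline(
      ep, mont, csd_params(cfg$csd_m, cfg$csd_lambda, cfg$csd_legendre_terms),
      swa_bd, artifact_mask = mask, subepoch_s = cfg$subepoch_length
    )
  }
  out
}

#' Analyze a simulated fixture tree
#'
#' Runs filtering, re-referencing, epoching, spectra, artifact screening and
#' SWA mapping (whole night and per cycle) for every subject directory under
#' `in_dir`, writing log-relative map TSVs and a sleep-parameter table.
#' Per-subject failures are logged and reported at the end; the run continues
#' past them.
#'
#' @param in_dir fixture tree from [run_simulate()].
#' @param out_dir output directory.
#' @param cfg an [analysis_config()].
#' @param csd also compute CSD SWA maps (slower).
#' @return list with `sleep_parameters` tibble and `failures` (named list of
#'   error messages, empty on full success), invisibly.
#' @export
run_analyze <- function(in_dir, out_dir, cfg = analysis_config(),
                        csd = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mont <- read_montage(file.path(in_dir, "montage.tsv"))
  subjects <- sort(list.dirs(in_dir, recursive = FALSE))
  # subject directories are those holding fixture files
  subjects <- subjects[file.exists(file.path(subjects, "recording.edf")) |
                       file.exists(file.path(subjects, "hypnogram.txt"))]
  failures <- list()
  sleep_rows <- list()
  for (sdir in subjects) {
    sid <- basename(sdir)
    res <- tryCatch({
      rec <- read_edf(file.path(sdir, "recording.edf"))
      hyp <- read_hypnogram(file.path(sdir, "hypnogram.txt"))
      analyze_subject(rec, hyp, mont, cfg, csd = csd)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[sid]] <- conditionMessage(res)
      message(sprintf("subject %s failed: %s", sid, conditionMessage(res)))
      next
    }
    odir <- file.path(out_dir, sid)
    dir.create(odir, showWarnings = FALSE)
    write_topomap(res$night, file.path(odir, "swa_night.tsv"))
    for (nm in names(res$cycles)) {
      write_topomap(res$cycles[[nm]], file.path(odir, paste0("swa_", nm, ".tsv")))
    }
    if (!is.null(res$csd)) {
      write_topomap(res$csd, file.path(odir, "csd_swa_night.tsv"))
    }
    utils::write.table(res$artifact_report, file.path(odir, "artifacts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sleep_rows[[sid]] <- mutate(res$sleep, subject_id = sid, .before = 1)
  }
  sleep_tbl <- dplyr::bind_rows(sleep_rows)
  utils::write.table(sleep_tbl, file.path(out_dir, "sleep_parameters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(sleep_parameters = sleep_tbl, failures = failures))
}

#' Cluster statistics over analyzed maps
#'
#' Loads the per-subject whole-night (and per-cycle) log-relative SWA maps
#' and the behavior table, runs the suprathreshold cluster permutation test,
#' summarizes significant clusters with cluster-mean correlations and partial
#' correlations for the configured covariates, and performs the per-cycle and
#' pooled-cycle analyses when every subject has the requested cycles.
#'
#' @param maps_dir output directory of [run_analyze()].
#' @param behavior_path behavior TSV.
#' @param montage_path montage TSV.
#' @param out_dir report directory.
#' @param cfg an [analysis_config()].
#' @param cycles cycle numbers for the per-cycle analysis (default 1:4).
#' @return list with the `cluster_test`, `cluster_summary`,
#'   `partial_correlations` and `per_cycle` results, invisibly.
#' @export
run_stats <- function(maps_dir, behavior_path, montage_path, out_dir,
                      cfg = analysis_config(), cycles = 1:4) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mont <- read_montage(montage_path)
  beh <- read_behavior(behavior_path)
  subjects <- sort(list.dirs(maps_dir, recursive = FALSE))
  sids <- basename(subjects)
  missing <- setdiff(sids, beh$subject_id)
  if (length(missing)) {
    stop_swatopo(sprintf("no behavior row for subject(s): %s",
                         paste(missing, collapse = ", ")),
                 "swatopo_validation_error")
  }
  beh <- beh[match(sids, beh$subject_id), ]
  maps <- do.call(rbind, lapply(subjects, function(sdir) {
    mp <- read_topomap(file.path(sdir, "swa_night.tsv"))
    stats::setNames(mp$value, mp$electrode)
  }))
  ds <- swa_dataset(maps, beh$score, mont = mont, subject_id = sids)
  graph <- adjacency_graph(mont, cfg$adjacency_mm)
  test <- cluster_permutation_test(
    ds, graph,
    alpha_electrode = cfg$alpha_electrode,
    alpha_cluster = 1 - cfg$cluster_percentile / 100,
    n_permutations = cfg$n_permutations, seed = cfg$seed
  )
  write_cluster_report(test, file.path(out_dir, "cluster_report.json"))
  rtab <- mutate(test$r_map,
                 supra = abs(.data$r) >= test$r_critical)
  utils::write.table(rtab, file.path(out_dir, "electrode_r.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  sig <- test$clusters[test$clusters$significant, ]
  cluster_summary <- NULL
  partials <- NULL
  per_cycle <- NULL
  if (nrow(sig)) {
    cl <- sig$electrodes[[1]]
    cluster_summary <- cluster_mean_correlation(ds, cl)
    cm <- rowMeans(ds$maps[, match(cl, ds$electrodes), drop = FALSE])
    covs <- intersect(c("age", "gender", "total_sleep_time"), names(beh))
    if (length(covs)) {
      partials <- dplyr::bind_rows(lapply(covs, function(cv) {
        mutate(partial_correlation(cm, beh$score, beh[[cv]]),
               covariate = cv, .before = 1)
      }))
      utils::write.table(partials, file.path(out_dir, "partial_correlations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    cyc_files <- sprintf("swa_cycle_%d.tsv", cycles)
    have_all <- all(vapply(subjects, function(sdir) {
      all(file.exists(file.path(sdir, cyc_files)))
    }, TRUE))
    if (have_all) {
      cycle_maps <- lapply(subjects, function(sdir) {
        out <- lapply(cycles, function(cyc) {
          read_topomap(file.path(sdir, sprintf("swa_cycle_%d.tsv", cyc)))
        })
        names(out) <- sprintf("cycle_%d", cycles)
        out
      })
      per_cycle <- per_cycle_analysis(cycle_maps, beh$score, cl, mont,
                                      cycles = cycles)
      utils::write.table(per_cycle$per_cycle,
                         file.path(out_dir, "per_cycle.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(cluster_summary, file.path(out_dir, "cluster_mean.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(cluster_test = test, cluster_summary = cluster_summary,
                 partial_correlations = partials, per_cycle = per_cycle))
}
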