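#' Read and write the package's delimited-text formats
#'
#' Trial tables travel as TSV with a header row; hypnograms as CSV with
#' columns `epoch_index` (0-based) and `state`; stimulus schedules as CSV
#' with `onset_s`, `freq_hz`, `level_db`.
#'
#' @param trials,hyp,schedule objects to write.
#' @param path file path.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_trials <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_trials <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname table_io
#' @export
write_hypnogram <- function(hyp, path) {
  write.csv(as.data.frame(hyp)[c("epoch_index", "state")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_hypnogram <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  h <- hypnogram(df$state)
  h$epoch_index <- df$epoch_index
  h
}

#' @rdname table_io
#' @export
write_schedule <- function(schedule, path) {
  write.csv(as.data.frame(schedule)[c("onset_s", "freq_hz", "level_db")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_schedule <- function(path) {
  sch <- read.csv(path, stringsAsFactors = FALSE)
  attr(sch, "stim_dur_s") <- 0.82
  attr(sch, "gap_s") <- 0.038
  attr(sch, "end_s") <- max(sch$onset_s) + 0.82
  class(sch) <- c("stimulus_schedule", "data.frame")
  sch
}

#' Analysis run configuration
#'
#' Collects every tunable analysis parameter with its default: 4-s
#' epochs, 0.25 Hz spectral bins, 500 bootstrap iterations and the 600-SD
#' factor for spectral outlier exclusion, 20 bootstrapped means and
#' 8-point smoothing for evoked responses, response-time cutoffs of 5 s
#' (gap task) and 20 s (silence task), and the 1.6--4 ms ABR window with
#' its 0.16 ms shift per 10 dB decrement.
#'
#' @param ... overrides of individual parameters.
#' @param seed integer seed governing all generators.
#' @return named list of class `run_config`.
#' @export
run_config <- function(..., seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    epoch_s = 4,
    spectral_bin_hz = 0.25,
    spectral_max_hz = 30,
    outlier_n_boot = 500,
    outlier_n_sd = 600,
    aer_n_boot = 20,
    aer_smooth_width = 8,
    gap_rt_cutoff_s = 5,
    silence_rt_cutoff_s = 20,
    abr_window_ms = c(1.6, 4),
    abr_shift_ms_per_10db = 0.16,
    abr_presence_k = 3,
    swa_band_hz = c(0.5, 4)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Run the full synthetic-data demonstration pipeline
#'
#' Generates behavioural, ABR and EEG data for a baseline and a
#' post-exposure condition, runs every analysis stage (behaviour scoring
#' and psychometric fits, tinnitus index, ABR metrics and change metrics,
#' sleep architecture and spectra, evoked-response magnitudes), writes
#' result tables under `out_dir`, and emits a JSON run manifest with the
#' seed and parameter provenance.
#'
#' @param config [run_config()].
#' @param out_dir output directory (created if needed); NULL skips
#'   writing.
#' @param eeg_duration_s duration of the simulated EEG recordings
#'   (default 2400 s to keep the demonstration light).
#' @param tinnitus_effect list of post-exposure ground-truth shifts:
#'   `threshold_shift_ms`, `nogap_gain`, `silence_drop` (see the methods
#'   vignette).
#' @return list with all stage outputs (`tindex`, `abr`, `sleep`, `aer`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         eeg_duration_s = 2400,
                         tinnitus_effect = list(threshold_shift_ms = 25,
                                                nogap_gain = 0.05,
                                                silence_drop = 0.15)) {
  seed <- config$seed
  gt_bl <- behaviour_ground_truth(seed = seed)
  thr_post <- pmin(gt_bl$threshold_ms + tinnitus_effect$threshold_shift_ms, 270)
  sil_post <- gt_bl$silence_correct
  sil_post[["silence"]] <- max(0, sil_post[["silence"]] -
                                 tinnitus_effect$silence_drop)
  gt_post <- behaviour_ground_truth(
    threshold_ms = thr_post,
    nogap_correct = min(1, gt_bl$nogap_correct + tinnitus_effect$nogap_gain),
    silence_correct = sil_post, seed = seed + 1L)

  gap_bl <- gen_gap_trials(gt_bl, condition = "BL")
  gap_post <- gen_gap_trials(gt_post, condition = "post-1")
  sil_bl <- gen_silence_trials(gt_bl, condition = "BL")
  sil_post_t <- gen_silence_trials(gt_post, condition = "post-1")
  ti <- compute_tinnitus_index(gap_bl, gap_post, sil_bl, sil_post_t)

  abr_bl <- gen_abr(abr_ground_truth(seed = seed), condition = "BL")
  thr_shift <- setNames(rep(10, length(abr_bl$ground_truth$threshold_db)),
                        names(abr_bl$ground_truth$threshold_db))
  abr_post <- gen_abr(abr_ground_truth(
    threshold_db = abr_bl$ground_truth$threshold_db + thr_shift,
    growth_uv_per_db = abr_bl$ground_truth$growth_uv_per_db * 0.7,
    seed = seed + 1L), condition = "post-1")
  met_bl <- abr_metrics(abr_bl, k = config$abr_presence_k)
  met_post <- abr_metrics(abr_post, k = config$abr_presence_k)
  abr_cmp <- abr_compare(met_bl, met_post)

  egt <- eeg_ground_truth(duration_s = eeg_duration_s, seed = seed)
  rec <- gen_eeg_recording(egt)
  sp <- epoch_spectra(rec$signals[["EEG-Frontal"]], rec$fs_hz,
                      max_freq_hz = config$spectral_max_hz)
  mask <- bootstrap_outlier_mask(sp, rec$hypnogram, "NREM",
                                 n_boot = config$outlier_n_boot,
                                 n_sd = config$outlier_n_sd, seed = seed)
  sleep_out <- list(
    percentages = state_percentages(rec$hypnogram),
    wake_episodes = episodes(rec$hypnogram, "Wake"),
    nrem_spectrum = state_spectrum(sp, rec$hypnogram, "NREM", mask),
    swa = swa_timecourse(sp, rec$hypnogram, mask)
  )

  sch <- stimulus_schedule(freq_hz = 4000, level_db = 60, repetitions = 60,
                           seed = seed)
  need <- ceiling((attr(sch, "end_s") + 10) / 4) * 4
  egt2 <- eeg_ground_truth(duration_s = max(eeg_duration_s, need),
                           seed = seed + 2L)
  rec2 <- gen_eeg_recording(egt2, schedule = sch)
  ev <- extract_trials(rec2$signals[["EEG-Frontal"]], rec2$fs_hz, sch,
                       rec2$hypnogram)
  grand <- colMeans(ev$trials)
  win <- derive_component_windows(grand, ev$t_s,
                                  smooth_width = config$aer_smooth_width)
  mt <- magnitude_table(ev, win, n_boot = config$aer_n_boot,
                        smooth_width = config$aer_smooth_width, seed = seed)
  aer_out <- list(windows = win, pooled = pool_magnitudes(mt, by = "state"))

  manifest <- list(package = "tinsleep",
                   version = as.character(utils::packageVersion("tinsleep")),
                   seed = seed, parameters = unclass(config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trials(gap_bl, file.path(out_dir, "gap_trials_bl.tsv"))
    write_trials(gap_post, file.path(out_dir, "gap_trials_post.tsv"))
    utils::write.table(as.data.frame(ti), file.path(out_dir, "tindex.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(met_bl$rms, file.path(out_dir, "abr_rms_bl.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_hypnogram(rec$hypnogram, file.path(out_dir, "hypnogram.csv"))
    utils::write.table(aer_out$pooled, file.path(out_dir, "aer_pooled.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(tindex = ti, abr = list(bl = met_bl, post = met_post,
                               compare = abr_cmp),
       sleep = sleep_out, aer = aer_out, manifest = manifest)
}
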