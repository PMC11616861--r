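#' Ground truth for the ABR generator
#'
#' Describes, per stimulus, a true threshold on the 10 dB level grid and a
#' waveform template built from Gabor-like deflections whose latencies at
#' the highest level lie inside the 1.6--4 ms response window. Below
#' threshold the averaged response is zero; above threshold the template is
#' scaled linearly with level (`growth_uv_per_db` per dB above threshold);
#' at threshold itself a just-detectable response of amplitude
#' `growth_uv_per_db * threshold_gain_db` is present, reflecting the
#' definition of threshold as the lowest level that elicits a response.
#' Latencies shift later by `latency_shift_ms` per 10 dB decrement, in
#' register with the analysis response window.
#'
#' @param threshold_db named numeric, true threshold (dB SPL, on
#'   \{40, ..., 90\} or `Inf` for "no response at any level") per stimulus.
#' @param components data.frame of template deflections with columns
#'   `latency_ms` (in \[1.6, 4\] at the highest level), `amp` (relative
#'   amplitude, the largest should be 1), `freq_hz` (carrier), `sigma_ms`
#'   (Gaussian envelope SD).
#' @param growth_uv_per_db amplitude growth above threshold (uV/dB).
#' @param threshold_gain_db dB-equivalent amplitude of the at-threshold
#'   response (default 1).
#' @param latency_shift_ms latency increase per 10 dB decrement (ms).
#' @param noise_sd_uv single-sweep noise SD (uV); the averaged waveform
#'   carries noise of SD `noise_sd_uv / sqrt(repetitions)`.
#' @param repetitions sweeps averaged per level (default 700).
#' @param fs_hz sampling rate (default 25000).
#' @param levels_db stimulus levels (default 40--90 in 10 dB steps).
#' @param t_range_ms waveform extent in ms relative to stimulus onset;
#'   includes a pre-stimulus baseline (default \[-1, 7\]).
#' @param seed integer seed.
#' @return object of class `abr_ground_truth`.
#' @export
abr_ground_truth <- function(threshold_db = c("1kHz" = 50, "4kHz" = 50,
                                              "8kHz" = 50, "16kHz" = 50,
                                              "BBN" = 40),
                             components = data.frame(
                               latency_ms = c(2.0, 2.7, 3.4),
                               amp = c(1, 0.7, 0.5),
                               freq_hz = c(900, 900, 800),
                               sigma_ms = c(0.18, 0.2, 0.22)),
                             growth_uv_per_db = 0.02,
                             threshold_gain_db = 1,
                             latency_shift_ms = 0.16,
                             noise_sd_uv = 1.2,
                             repetitions = 700L,
                             fs_hz = 25000,
                             levels_db = seq(40, 90, by = 10),
                             t_range_ms = c(-1, 7),
                             seed = 1L) {
  if (repetitions < 1) stop("repetitions must be >= 1", call. = FALSE)
  bad <- is.finite(threshold_db) & !(threshold_db %in% levels_db)
  if (any(bad)) {
    stop("thresholds must lie on the level grid (or be Inf)", call. = FALSE)
  }
  max_shift <- latency_shift_ms * (max(levels_db) - min(levels_db)) / 10
  if (any(components$latency_ms < 1.6) || any(components$latency_ms > 4)) {
    stop("template latencies must lie in [1.6, 4] ms at the highest level",
         call. = FALSE)
  }
  if (max(components$latency_ms) + max_shift > t_range_ms[2]) {
    stop("waveform extent too short for the shifted response window",
         call. = FALSE)
  }
  structure(list(threshold_db = threshold_db, components = components,
                 growth_uv_per_db = growth_uv_per_db,
                 threshold_gain_db = threshold_gain_db,
                 latency_shift_ms = latency_shift_ms,
                 noise_sd_uv = noise_sd_uv, repetitions = as.integer(repetitions),
                 fs_hz = fs_hz, levels_db = levels_db, t_range_ms = t_range_ms,
                 seed = as.integer(seed)),
            class = "abr_ground_truth")
}

# template evaluated on time axis t_ms with latencies shifted by shift_ms
abr_template <- function(t_ms, components, shift_ms = 0) {
  y <- numeric(length(t_ms))
  for (i in seq_len(nrow(components))) {
    mu <- components$latency_ms[i] + shift_ms
    y <- y + components$amp[i] *
      exp(-((t_ms - mu)^2) / (2 * components$sigma_ms[i]^2)) *
      cos(2 * pi * components$freq_hz[i] * (t_ms - mu) / 1000)
  }
  y
}

#' Generate an averaged-waveform ABR dataset
#'
#' For each stimulus and level the averaged waveform is the shifted, scaled
#' template plus Gaussian noise of SD `noise_sd_uv / sqrt(repetitions)`
#' (the residual noise of a 700-sweep average).
#'
#' @param gt [abr_ground_truth()].
#' @param animal,condition labels attached to the dataset.
#' @return object of class `abr_dataset`: list with `t_ms` (time axis),
#'   `waveforms` (list by stimulus of matrices level x sample, in uV),
#'   `levels_db`, `fs_hz`, `repetitions`, labels, and the ground truth.
#' @export
gen_abr <- function(gt, animal = "F1", condition = "BL") {
  stopifnot(inherits(gt, "abr_ground_truth"))
  set.seed(substream_seed(gt$seed, paste0("abr:", animal, condition)))
  t_ms <- seq(gt$t_range_ms[1], gt$t_range_ms[2], by = 1000 / gt$fs_hz)
  max_level <- max(gt$levels_db)
  waveforms <- list()
  for (stim in names(gt$threshold_db)) {
    thr <- gt$threshold_db[[stim]]
    mat <- matrix(0, nrow = length(gt$levels_db), ncol = length(t_ms),
                  dimnames = list(gt$levels_db, NULL))
    for (i in seq_along(gt$levels_db)) {
      lev <- gt$levels_db[i]
      shift <- gt$latency_shift_ms * (max_level - lev) / 10
      amp_db <- if (!is.finite(thr) || lev < thr) 0
                else if (lev == thr) gt$threshold_gain_db
                else lev - thr
      sig <- amp_db * gt$growth_uv_per_db * abr_template(t_ms, gt$components, shift)
      noise <- rnorm(length(t_ms), 0, gt$noise_sd_uv / sqrt(gt$repetitions))
      mat[i, ] <- sig + noise
    }
    waveforms[[stim]] <- mat
  }
  structure(list(t_ms = t_ms, waveforms = waveforms, levels_db = gt$levels_db,
                 fs_hz = gt$fs_hz, repetitions = gt$repetitions,
                 animal = animal, condition = condition, ground_truth = gt),
            class = "abr_dataset")
}
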