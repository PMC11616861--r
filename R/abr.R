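#' ABR response window for a stimulus level
#'
#' The response window is 1.6--4 ms after stimulus onset at the highest
#' level, shifted 0.16 ms later for each 10 dB decrement to account for
#' longer response latencies at low levels.
#'
#' @param level_db stimulus level (dB SPL, on the 10 dB grid).
#' @param max_level_db highest level of the series (default 90).
#' @param shift_ms_per_10db latency shift per 10 dB decrement (default
#'   0.16 ms).
#' @param base_window_ms window at the highest level (default c(1.6, 4)).
#' @return numeric `c(start_ms, end_ms)`.
#' @export
response_window <- function(level_db, max_level_db = 90,
                            shift_ms_per_10db = 0.16,
                            base_window_ms = c(1.6, 4)) {
  if (level_db > max_level_db || (max_level_db - level_db) %% 10 != 0) {
    stop("level must be on the 10 dB grid at or below the maximum level",
         call. = FALSE)
  }
  shift <- shift_ms_per_10db * (max_level_db - level_db) / 10
  base_window_ms + shift
}

#' RMS magnitude of a waveform segment
#'
#' Square root of the mean squared sample value inside the window
#' (half-open `[start, end)` on the sample grid).
#'
#' @param waveform numeric samples (uV).
#' @param t_ms time axis (ms), same length as `waveform`.
#' @param window_ms `c(start_ms, end_ms)`.
#' @return RMS in uV.
#' @export
rms_magnitude <- function(waveform, t_ms, window_ms) {
  idx <- t_ms >= window_ms[1] & t_ms < window_ms[2]
  if (!any(idx)) stop("empty response window", call. = FALSE)
  sqrt(mean(waveform[idx]^2))
}

#' Area under the level-response curve
#'
#' Trapezoidal area under RMS magnitude versus stimulus level over the
#' available levels. Levels with missing RMS are skipped with a warning
#' (piecewise trapezoid over the remaining points).
#'
#' @param rms_by_level named numeric (names = levels in dB) or data.frame
#'   with columns `level_db`, `rms_uv`.
#' @return area in uV dB.
#' @export
level_response_auc <- function(rms_by_level) {
  if (is.data.frame(rms_by_level)) {
    lev <- rms_by_level$level_db
    rms <- rms_by_level$rms_uv
  } else {
    lev <- as.numeric(names(rms_by_level))
    rms <- as.numeric(rms_by_level)
  }
  ok <- is.finite(rms)
  if (any(!ok)) warning("skipping level(s) with missing RMS")
  lev <- lev[ok]; rms <- rms[ok]
  if (length(lev) < 2) stop("need at least 2 levels for the AUC", call. = FALSE)
  o <- order(lev)
  pracma::trapz(lev[o], rms[o])
}

#' Per-stimulus ABR magnitudes, AUCs and automated thresholds
#'
#' For each stimulus: RMS in the level-shifted response window per level,
#' the trapezoidal level-response AUC, and an automated threshold
#' surrogate (see [estimate_threshold()]). The thresholds produced here
#' are an automated surrogate for blind manual scoring, and outputs are
#' labelled as such.
#'
#' @param dataset [gen_abr()] dataset (class `abr_dataset`).
#' @param k baseline SD multiple for the wave-presence criterion.
#' @return list of class `abr_metrics`: `rms` (data.frame `stimulus`,
#'   `level_db`, `rms_uv`), `auc` (data.frame `stimulus`, `auc_uvdb`),
#'   `thresholds` (data.frame `stimulus`, `threshold_db`,
#'   `method = "automated-surrogate"`).
#' @export
abr_metrics <- function(dataset, k = 3) {
  stopifnot(inherits(dataset, "abr_dataset"))
  rms_rows <- list(); auc_rows <- list(); thr_rows <- list()
  max_level <- max(dataset$levels_db)
  for (stim in names(dataset$waveforms)) {
    mat <- dataset$waveforms[[stim]]
    rms <- vapply(seq_along(dataset$levels_db), function(i) {
      rms_magnitude(mat[i, ], dataset$t_ms,
                    response_window(dataset$levels_db[i], max_level))
    }, numeric(1))
    rms_rows[[stim]] <- data.frame(stimulus = stim,
                                   level_db = dataset$levels_db,
                                   rms_uv = rms)
    auc_rows[[stim]] <- data.frame(stimulus = stim,
                                   auc_uvdb = level_response_auc(
                                     setNames(rms, dataset$levels_db)))
    thr_rows[[stim]] <- data.frame(stimulus = stim,
                                   threshold_db = estimate_threshold(dataset,
                                                                     stim,
                                                                     k = k),
                                   method = "automated-surrogate")
  }
  structure(list(rms = do.call(rbind, c(rms_rows, make.row.names = FALSE)),
                 auc = do.call(rbind, c(auc_rows, make.row.names = FALSE)),
                 thresholds = do.call(rbind, c(thr_rows,
                                               make.row.names = FALSE)),
                 animal = dataset$animal, condition = dataset$condition),
            class = "abr_metrics")
}

#' Automated ABR threshold surrogate
#'
#' A wave is considered present at a level when the RMS in that level's
#' response window exceeds the mean plus `k` SD of the per-level
#' pre-stimulus RMS values (baseline window `[-1, 0)` ms by default; in a
#' noiseless series the criterion reduces to RMS > 0). The threshold is
#' the lowest level at which the wave is present and remains present at
#' all higher levels; 90 dB SPL (the highest level used) if the wave is
#' present at no level. This is an automated surrogate for blind manual
#' scoring, not a reproduction of it.
#'
#' @param dataset `abr_dataset`.
#' @param stimulus stimulus name.
#' @param k baseline SD multiple (default 3).
#' @param baseline_ms pre-stimulus baseline window (default c(-1, 0)).
#' @return threshold in dB SPL.
#' @export
estimate_threshold <- function(dataset, stimulus, k = 3,
                               baseline_ms = c(-1, 0)) {
  mat <- dataset$waveforms[[stimulus]]
  if (is.null(mat)) stop("unknown stimulus: ", stimulus, call. = FALSE)
  if (min(dataset$t_ms) > baseline_ms[1]) {
    stop("waveforms lack a pre-stimulus baseline segment", call. = FALSE)
  }
  levels_db <- dataset$levels_db
  max_level <- max(levels_db)
  base_rms <- apply(mat, 1, rms_magnitude, t_ms = dataset$t_ms,
                    window_ms = baseline_ms)
  crit <- mean(base_rms) + k * sd(base_rms)
  resp_rms <- vapply(seq_along(levels_db), function(i) {
    rms_magnitude(mat[i, ], dataset$t_ms,
                  response_window(levels_db[i], max_level))
  }, numeric(1))
  present <- resp_rms > crit
  # lowest level present with all higher levels also present
  ok <- rev(cumprod(rev(present))) == 1
  if (!any(ok)) return(max_level)
  min(levels_db[ok])
}

#' ABR threshold change metric
#'
#' Average change in thresholds across stimuli. The primary value is the
#' threshold *elevation*, `mean(post) - mean(BL)` (positive = hearing
#' worsened); the literal difference `mean(BL) - mean(post)` is returned
#' alongside as `literal`, since the two sign conventions are both in
#' circulation.
#'
#' @param bl_thresholds,post_thresholds named numeric thresholds (dB SPL)
#'   per stimulus; the stimulus sets must match.
#' @return list with `elevation_db` and `literal_db` (= -elevation).
#' @export
m_thresholds <- function(bl_thresholds, post_thresholds) {
  if (!setequal(names(bl_thresholds), names(post_thresholds))) {
    stop("baseline and post threshold stimulus sets differ", call. = FALSE)
  }
  post_thresholds <- post_thresholds[names(bl_thresholds)]
  elev <- mean(post_thresholds) - mean(bl_thresholds)
  list(elevation_db = elev, literal_db = -elev)
}

#' ABR magnitude change metric
#'
#' `M(ABRmagnitude) = (Post / BL - 1) x 100`, where Post and BL are
#' level-response AUCs averaged across all stimuli. Positive values
#' indicate a response increase in percent; negative values a reduced
#' response (evidence for hearing loss).
#'
#' @param bl_auc_mean,post_auc_mean mean AUC across stimuli; baseline must
#'   be positive.
#' @return percent change.
#' @export
m_abr_magnitude <- function(bl_auc_mean, post_auc_mean) {
  if (!is.finite(bl_auc_mean) || bl_auc_mean <= 0) {
    stop("M(ABRmagnitude) undefined: baseline AUC must be > 0", call. = FALSE)
  }
  (post_auc_mean / bl_auc_mean - 1) * 100
}

#' Compare two ABR metric sets
#'
#' Computes the threshold-change and magnitude-change metrics between a
#' baseline and a post-exposure [abr_metrics()] result. Click stimuli are
#' excluded from the averages by default (the change metrics are defined
#' over the NBN and BBN stimuli).
#'
#' @param bl,post `abr_metrics` objects.
#' @param exclude regular expression of stimulus names to exclude
#'   (default clicks).
#' @return list with `m_thresholds` (elevation + literal) and
#'   `m_abr_magnitude` (percent).
#' @export
abr_compare <- function(bl, post, exclude = "^click") {
  pick <- function(m) {
    keep <- !grepl(exclude, m$thresholds$stimulus, ignore.case = TRUE)
    list(thr = setNames(m$thresholds$threshold_db[keep],
                        m$thresholds$stimulus[keep]),
         auc = setNames(m$auc$auc_uvdb[!grepl(exclude, m$auc$stimulus,
                                              ignore.case = TRUE)],
                        m$auc$stimulus[!grepl(exclude, m$auc$stimulus,
                                              ignore.case = TRUE)]))
  }
  b <- pick(bl); p <- pick(post)
  list(m_thresholds = m_thresholds(b$thr, p$thr),
       m_abr_magnitude = m_abr_magnitude(mean(b$auc), mean(p$auc)))
}
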