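#' Extract stimulus-locked EEG trials
#'
#' Cuts one segment per stimulus over \[-0.5, +5\] s around onset,
#' downsamples by a factor of 2, assigns the vigilance state of the 4-s
#' epoch containing the onset, and drops trials whose onset epoch is an
#' artefact (counted) or that run past the recording edge (warned).
#'
#' @param eeg numeric EEG signal (uV).
#' @param fs_hz sampling rate of `eeg`.
#' @param schedule [stimulus_schedule()].
#' @param hyp [hypnogram()] aligned with the EEG clock.
#' @param window_s trial window relative to onset (default c(-0.5, 5)).
#' @param downsample integer decimation factor (default 2).
#' @return object of class `evoked_set`: list with `trials` (matrix
#'   trial x sample), `t_s` (time axis), `fs_hz` (after decimation),
#'   `info` (data.frame `onset_s`, `freq_hz`, `level_db`, `state`),
#'   `n_artefact_dropped`, `n_edge_dropped`.
#' @export
extract_trials <- function(eeg, fs_hz, schedule, hyp,
                           window_s = c(-0.5, 5), downsample = 2L) {
  i_rel <- seq(round(window_s[1] * fs_hz), round(window_s[2] * fs_hz))
  keep_ds <- seq(1, length(i_rel), by = downsample)
  t_s <- i_rel[keep_ds] / fs_hz
  n <- length(eeg)
  rows <- list(); info <- list()
  n_art <- 0L; n_edge <- 0L
  for (k in seq_len(nrow(schedule))) {
    onset <- schedule$onset_s[k]
    i0 <- round(onset * fs_hz) + 1L
    idx <- i0 + i_rel
    if (idx[1] < 1 || idx[length(idx)] > n) {
      n_edge <- n_edge + 1L
      next
    }
    ep <- floor(onset / EPOCH_LEN_S) + 1L
    state <- hyp$state[ep]
    if (is.na(state) || state == "Artefact") {
      n_art <- n_art + 1L
      next
    }
    rows[[length(rows) + 1L]] <- eeg[idx][keep_ds]
    info[[length(info) + 1L]] <- data.frame(onset_s = onset,
                                            freq_hz = schedule$freq_hz[k],
                                            level_db = schedule$level_db[k],
                                            state = state)
  }
  if (n_edge > 0) warning(n_edge, " trial(s) dropped at recording edge")
  structure(list(trials = do.call(rbind, rows), t_s = t_s,
                 fs_hz = fs_hz / downsample,
                 info = do.call(rbind, info),
                 n_artefact_dropped = n_art, n_edge_dropped = n_edge),
            class = "evoked_set")
}

#' Bootstrapped mean traces for a trial group
#'
#' Draws `n_boot` means of with-replacement resamples (each of the full
#' group size) of the group's trials; the set of bootstrapped means
#' serves as a representative signal sample with reduced noise that still
#' reflects the variability of the original trials.
#'
#' @param set [extract_trials()] result.
#' @param which logical or integer index selecting the group's trials
#'   (e.g. `set$info$state == "Wake"`); default all trials.
#' @param n_boot number of bootstrapped means (default 20).
#' @param seed integer seed.
#' @return matrix `n_boot` x samples; NULL if the group is empty.
#' @export
bootstrap_group_means <- function(set, which = NULL, n_boot = 20, seed = 1L) {
  tr <- set$trials
  if (!is.null(which)) tr <- tr[which, , drop = FALSE]
  if (is.null(tr) || nrow(tr) == 0) return(NULL)
  set.seed(substream_seed(seed, "aer_boot"))
  out <- matrix(0, nrow = n_boot, ncol = ncol(tr))
  for (b in seq_len(n_boot)) {
    out[b, ] <- colMeans(tr[sample(nrow(tr), replace = TRUE), , drop = FALSE])
  }
  out
}

#' Moving-average smoothing
#'
#' Centred moving average over `width` samples (default 8); at the edges
#' the window shrinks to the available samples.
#'
#' @param trace numeric vector.
#' @param width window width in samples.
#' @return smoothed trace of the same length.
#' @export
smooth_trace <- function(trace, width = 8L) {
  n <- length(trace)
  if (n < width) stop("trace shorter than the smoothing window", call. = FALSE)
  half_l <- floor((width - 1) / 2)
  half_r <- width - 1L - half_l
  cs <- cumsum(c(0, trace))
  i <- seq_len(n)
  lo <- pmax(i - half_l, 1L)
  hi <- pmin(i + half_r, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Peak-to-subsequent-trough magnitude per response component
#'
#' Within each component window, the maximum of the trace is located and
#' then the minimum occurring after that maximum (up to the window end).
#' The magnitude is max minus subsequent min (>= 0); if the maximum falls
#' on the last sample of the window the magnitude is missing.
#'
#' @param trace numeric trace (typically a smoothed bootstrapped mean).
#' @param t_s time axis of `trace` (s relative to onset).
#' @param windows data.frame with `component`, `start_s`, `end_s`.
#' @return data.frame `component`, `magnitude`, `peak_t_s`, `trough_t_s`.
#' @export
component_magnitudes <- function(trace, t_s, windows) {
  out <- lapply(seq_len(nrow(windows)), function(k) {
    sel <- which(t_s >= windows$start_s[k] & t_s <= windows$end_s[k])
    if (!length(sel)) stop("component window contains no samples",
                           call. = FALSE)
    seg <- trace[sel]
    i_max <- which.max(seg)
    if (i_max == length(seg)) {
      return(data.frame(component = windows$component[k],
                        magnitude = NA_real_, peak_t_s = t_s[sel[i_max]],
                        trough_t_s = NA_real_))
    }
    after <- seg[(i_max + 1):length(seg)]
    i_min <- which.min(after) + i_max
    data.frame(component = windows$component[k],
               magnitude = seg[i_max] - seg[i_min],
               peak_t_s = t_s[sel[i_max]], trough_t_s = t_s[sel[i_min]])
  })
  do.call(rbind, out)
}

#' Derive per-animal component windows from a grand-mean trace
#'
#' Detects peaks on the smoothed grand mean within `search_s` (default
#' 0--0.5 s post-onset) using a minimum-prominence criterion (default
#' 2 x the pre-stimulus SD of the smoothed trace), and places windows of
#' `half_width_s` around up to `max_components` successive peaks,
#' truncated at the midpoints between neighbouring peaks so that windows
#' never overlap.
#'
#' @param trace grand-mean trace.
#' @param t_s time axis (s relative to onset).
#' @param search_s search window post-onset (default c(0, 0.5)).
#' @param max_components maximum number of components (default 3).
#' @param half_width_s half-width of each window (default 0.08 s).
#' @param min_prominence optional absolute prominence; default 2 x SD of
#'   the smoothed pre-stimulus trace.
#' @param smooth_width smoothing window (samples, default 8).
#' @return data.frame `component` ("R1", "R2", "R3"), `start_s`, `end_s`,
#'   `peak_t_s`; zero rows if no peaks are detected.
#' @export
derive_component_windows <- function(trace, t_s, search_s = c(0, 0.5),
                                     max_components = 3L,
                                     half_width_s = 0.08,
                                     min_prominence = NULL,
                                     smooth_width = 8L) {
  sm <- smooth_trace(trace, smooth_width)
  if (is.null(min_prominence)) {
    pre <- sm[t_s < 0]
    min_prominence <- if (length(pre) > 1) 2 * sd(pre) else 0
  }
  sel <- t_s >= search_s[1] & t_s <= search_s[2]
  seg <- sm[sel]
  ts_seg <- t_s[sel]
  # floor guards against ripple peaks when the pre-stimulus trace is quiet
  height <- max(min_prominence, 0.1 * max(seg))
  pk <- pracma::findpeaks(seg, minpeakheight = height,
                          minpeakdistance = 3L)
  empty <- data.frame(component = character(0), start_s = numeric(0),
                      end_s = numeric(0), peak_t_s = numeric(0))
  if (is.null(pk)) return(empty)
  pk <- pk[order(pk[, 2]), , drop = FALSE]
  lat <- ts_seg[pk[, 2]]
  lat <- head(lat, max_components)
  n <- length(lat)
  start_s <- pmax(lat - half_width_s, search_s[1])
  end_s <- pmin(lat + half_width_s, search_s[2])
  if (n > 1) {
    mid <- (lat[-n] + lat[-1]) / 2
    end_s[-n] <- pmin(end_s[-n], mid)
    start_s[-1] <- pmax(start_s[-1], mid)
  }
  data.frame(component = paste0("R", seq_len(n)), start_s = start_s,
             end_s = end_s, peak_t_s = lat)
}

#' Magnitude table over groups, components and bootstrap replicates
#'
#' For each group (unique combination of `group_by` columns of the trial
#' info) draws `n_boot` bootstrapped means, smooths each, and measures
#' component magnitudes. Optionally screens trials first, retaining only
#' those whose per-trial SD does not exceed `sd_screen` times the average
#' trial SD.
#'
#' @param set [extract_trials()] result.
#' @param windows component windows (see [derive_component_windows()]).
#' @param group_by info columns defining groups (default
#'   `c("freq_hz", "level_db", "state")`).
#' @param n_boot bootstrapped means per group (default 20).
#' @param smooth_width smoothing window (default 8 samples).
#' @param sd_screen optional multiple for the trial-SD screen (e.g. 2);
#'   NULL disables screening.
#' @param seed integer seed.
#' @return data.frame of class `magnitude_table`: group columns,
#'   `replicate`, `component`, `magnitude`, `n_trials`.
#' @export
magnitude_table <- function(set, windows,
                            group_by = c("freq_hz", "level_db", "state"),
                            n_boot = 20, smooth_width = 8L, sd_screen = NULL,
                            seed = 1L) {
  info <- set$info
  trials <- set$trials
  if (!is.null(sd_screen)) {
    tsd <- apply(trials, 1, sd)
    keep <- tsd <= sd_screen * mean(tsd)
    trials <- trials[keep, , drop = FALSE]
    info <- info[keep, , drop = FALSE]
  }
  key <- interaction(info[group_by], drop = TRUE)
  out <- list()
  for (g in levels(key)) {
    rows <- which(key == g)
    bm <- bootstrap_group_means(list(trials = trials[rows, , drop = FALSE]),
                                n_boot = n_boot,
                                seed = substream_seed(seed, g))
    if (is.null(bm)) next
    for (b in seq_len(nrow(bm))) {
      mg <- component_magnitudes(smooth_trace(bm[b, ], smooth_width),
                                 set$t_s, windows)
      rec <- data.frame(info[rows[1], group_by, drop = FALSE], replicate = b,
                        mg, n_trials = length(rows), row.names = NULL)
      out[[length(out) + 1L]] <- rec
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("magnitude_table", "data.frame")
  res
}

#' Pool bootstrap magnitudes
#'
#' Pooled mean and SEM of the retained bootstrap-replicate magnitudes in
#' each cell after collapsing over the given keys (e.g. components, sound
#' level and stimulus type, leaving vigilance state).
#'
#' @param table [magnitude_table()].
#' @param by column(s) to keep (default `"state"`).
#' @return data.frame `by` columns, `n`, `mean`, `sem`.
#' @export
pool_magnitudes <- function(table, by = "state") {
  tab <- table[!is.na(table$magnitude), , drop = FALSE]
  key <- interaction(tab[by], drop = TRUE)
  out <- lapply(levels(key), function(g) {
    v <- tab$magnitude[key == g]
    cbind(tab[which(key == g)[1], by, drop = FALSE],
          n = length(v), mean = mean(v),
          sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else 0)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
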