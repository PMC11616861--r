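#' Time spent in each vigilance state
#'
#' Percentages are computed over non-artefact epochs; artefact time is
#' reported separately as a percentage of all epochs. Total sleep is
#' NREM + REM + REM2.
#'
#' @param hyp [hypnogram()].
#' @return list with `percent` (named: Wake, NREM, REM, REM2),
#'   `sleep_percent`, `artefact_percent`, `n_epochs`.
#' @export
state_percentages <- function(hyp) {
  states <- hyp$state
  scored <- states[states != "Artefact"]
  if (!length(scored)) {
    stop("all epochs are artefacts; state percentages undefined",
         call. = FALSE)
  }
  tab <- table(factor(scored, levels = setdiff(VIGILANCE_STATES, "Artefact")))
  pct <- 100 * as.numeric(tab) / length(scored)
  names(pct) <- names(tab)
  list(percent = pct,
       sleep_percent = sum(pct[c("NREM", "REM", "REM2")]),
       artefact_percent = 100 * mean(states == "Artefact"),
       n_epochs = length(states))
}

#' Episodes of a vigilance state
#'
#' Maximal runs of the target state. By default artefact epochs lying
#' between two epochs of the target state bridge the run (they do not
#' terminate the episode) but are excluded from its duration. The episode
#' duration histogram uses configurable bin edges in minutes.
#'
#' @param hyp [hypnogram()].
#' @param state target state (e.g. `"Wake"`).
#' @param bridge_artefacts logical; bridge runs across artefact epochs
#'   (default TRUE).
#' @param hist_breaks_min histogram bin edges in minutes (default
#'   c(0, 1, 5, 15, 30, Inf)).
#' @return list with `episodes` (data.frame `start_epoch` (1-based),
#'   `end_epoch`, `n_epochs` (state epochs only), `duration_min`),
#'   `count`, and `histogram` (named counts per duration bin).
#' @export
episodes <- function(hyp, state, bridge_artefacts = TRUE,
                     hist_breaks_min = c(0, 1, 5, 15, 30, Inf)) {
  epoch_s <- attr(hyp, "epoch_s") %||% EPOCH_LEN_S
  s <- hyp$state
  is_target <- s == state
  is_art <- s == "Artefact"
  if (bridge_artefacts) {
    # an artefact epoch joins a run iff flanked by target epochs
    # (possibly across further artefact epochs)
    run <- is_target
    i <- 1L
    n <- length(s)
    while (i <= n) {
      if (is_art[i]) {
        j <- i
        while (j <= n && is_art[j]) j <- j + 1L
        if (i > 1L && run[i - 1L] && j <= n && is_target[j]) {
          run[i:(j - 1L)] <- TRUE
        }
        i <- j
      } else {
        i <- i + 1L
      }
    }
  } else {
    run <- is_target
  }
  r <- rle(run)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  ep <- data.frame(start_epoch = starts[keep], end_epoch = ends[keep])
  ep$n_epochs <- vapply(seq_len(nrow(ep)), function(k) {
    sum(is_target[ep$start_epoch[k]:ep$end_epoch[k]])
  }, integer(1))
  ep$duration_min <- ep$n_epochs * epoch_s / 60
  hist_counts <- table(cut(ep$duration_min, breaks = hist_breaks_min,
                           right = FALSE))
  list(episodes = ep, count = nrow(ep), histogram = hist_counts)
}

#' Per-epoch EEG power spectra (4-s Hanning periodogram)
#'
#' Splits the signal into consecutive 4-s epochs and computes a
#' Hann-tapered one-sided periodogram per epoch at the native 0.25 Hz
#' resolution. Power is normalised so that the bins sum to the signal
#' variance (uV^2 per 0.25 Hz bin); bins up to `max_freq_hz` are
#' returned. Input at sampling rates other than 256 Hz is resampled first
#' (polyphase anti-aliased resampling).
#'
#' @param x numeric EEG signal (uV).
#' @param fs_hz sampling rate of `x`.
#' @param max_freq_hz highest analysed frequency (default 30).
#' @param target_fs_hz analysis rate (default 256).
#' @return object of class `epoch_spectra`: list with `power` (matrix
#'   epochs x bins), `freq_hz` (bin centres), `epoch_s`.
#' @export
epoch_spectra <- function(x, fs_hz = 256, max_freq_hz = 30,
                          target_fs_hz = 256) {
  if (fs_hz != target_fs_hz) {
    x <- signal::resample(x, target_fs_hz, fs_hz)
    fs_hz <- target_fs_hz
  }
  nper <- EPOCH_LEN_S * fs_hz
  n_epochs <- floor(length(x) / nper)
  if (n_epochs < 1) stop("signal shorter than one 4-s epoch", call. = FALSE)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nper) / (nper + 1)))  # Hann taper
  s2 <- sum(w^2)
  freq <- (0:(nper / 2)) * fs_hz / nper
  keep <- freq <= max_freq_hz
  pw <- matrix(0, nrow = n_epochs, ncol = sum(keep))
  for (e in seq_len(n_epochs)) {
    seg <- x[((e - 1) * nper + 1):(e * nper)]
    X <- fft(seg * w)[seq_len(nper / 2 + 1)]
    p <- Mod(X)^2 / (nper * s2)
    p[2:(nper / 2)] <- 2 * p[2:(nper / 2)]   # one-sided
    pw[e, ] <- p[keep]
  }
  structure(list(power = pw, freq_hz = freq[keep], epoch_s = EPOCH_LEN_S),
            class = "epoch_spectra")
}

#' Bootstrap outlier mask for state spectra
#'
#' For each frequency bin of the given state, the mean and its standard
#' deviation are estimated from a 500-iteration bootstrap over epochs
#' (resampling epochs with replacement; the SD is the bootstrap SD of the
#' mean). Epoch values outside mean +/- `n_sd` x SD are masked. Masking
#' applies per bin, not per epoch, and removes only extreme outliers.
#'
#' @param spectra [epoch_spectra()].
#' @param hyp [hypnogram()] aligned with the spectra.
#' @param state target state.
#' @param n_boot bootstrap iterations (default 500).
#' @param n_sd exclusion multiple (default 600).
#' @param min_epochs minimum state epochs required (default 10); below
#'   this the mask is all-valid with a warning.
#' @param seed seed for the bootstrap resampling.
#' @return logical matrix (epochs x bins): TRUE = valid. Rows for epochs
#'   not in the state are NA.
#' @export
bootstrap_outlier_mask <- function(spectra, hyp, state, n_boot = 500,
                                   n_sd = 600, min_epochs = 10, seed = 1L) {
  idx <- which(hyp$state[seq_len(nrow(spectra$power))] == state)
  mask <- matrix(NA, nrow = nrow(spectra$power), ncol = ncol(spectra$power))
  if (length(idx) < min_epochs) {
    warning("fewer than ", min_epochs, " epochs of state ", state,
            "; nothing masked")
    mask[idx, ] <- TRUE
    return(mask)
  }
  set.seed(substream_seed(seed, paste0("outlier:", state)))
  vals <- spectra$power[idx, , drop = FALSE]
  nb <- matrix(0, nrow = n_boot, ncol = ncol(vals))
  for (b in seq_len(n_boot)) {
    nb[b, ] <- colMeans(vals[sample(nrow(vals), replace = TRUE), ,
                             drop = FALSE])
  }
  m <- colMeans(nb)
  s <- apply(nb, 2, sd)
  lo <- m - n_sd * s
  hi <- m + n_sd * s
  ok <- sweep(vals, 2, lo, ">=") & sweep(vals, 2, hi, "<=")
  mask[idx, ] <- ok
  mask
}

#' Mean state spectrum with standard errors
#'
#' Per-bin mean and standard error across the valid (unmasked) epoch
#' values of a state, with an optional variant in which adjacent 0.25 Hz
#' bins are merged pairwise into 0.5 Hz bins.
#'
#' @param spectra [epoch_spectra()].
#' @param hyp [hypnogram()].
#' @param state target state.
#' @param mask optional mask from [bootstrap_outlier_mask()].
#' @return list with `freq_hz`, `mean`, `se`, `n_epochs`, and `merged`
#'   (data.frame `freq_hz`, `mean`, `se` at 0.5 Hz).
#' @export
state_spectrum <- function(spectra, hyp, state, mask = NULL) {
  idx <- which(hyp$state[seq_len(nrow(spectra$power))] == state)
  if (!length(idx)) return(NULL)
  vals <- spectra$power[idx, , drop = FALSE]
  if (!is.null(mask)) {
    vals[!mask[idx, , drop = FALSE]] <- NA
  }
  mu <- colMeans(vals, na.rm = TRUE)
  nn <- colSums(!is.na(vals))
  se <- apply(vals, 2, sd, na.rm = TRUE) / sqrt(pmax(nn, 1))
  # pair bins above DC: (0.25, 0.5) -> 0.5, (0.75, 1.0) -> 1.0, ...
  f <- spectra$freq_hz
  pair_hi <- seq(3, length(f), by = 2)
  pair_hi <- pair_hi[pair_hi <= length(f)]
  merged <- data.frame(
    freq_hz = f[pair_hi],
    mean = (mu[pair_hi - 1] + mu[pair_hi]) / 2,
    se = sqrt(se[pair_hi - 1]^2 + se[pair_hi]^2) / 2
  )
  list(freq_hz = f, mean = mu, se = se, n_epochs = length(idx),
       merged = merged)
}

#' NREM slow-wave activity time course
#'
#' SWA is the mean power over the 0.5--4 Hz bins, averaged across NREM
#' epochs within each 15-minute interval; intervals without NREM are
#' missing. The 15-minute values are then merged into 1-hour bins (the
#' mean of the available 15-min values, up to 4 per hour).
#'
#' @param spectra [epoch_spectra()].
#' @param hyp [hypnogram()].
#' @param mask optional outlier mask.
#' @param band SWA band (default c(0.5, 4) Hz).
#' @param interval_s fine interval (default 900 s = 15 min).
#' @param merge_intervals number of fine intervals per merged bin
#'   (default 4 = 1 hour).
#' @param state state over which SWA is computed (default NREM).
#' @return list with `fine` (data.frame `t_start_s`, `swa`, `n_epochs`)
#'   and `merged` (data.frame `t_start_s`, `swa`).
#' @export
swa_timecourse <- function(spectra, hyp, mask = NULL, band = c(0.5, 4),
                           interval_s = 900, merge_intervals = 4,
                           state = "NREM") {
  n_ep <- nrow(spectra$power)
  bins <- spectra$freq_hz >= band[1] & spectra$freq_hz <= band[2]
  vals <- spectra$power[, bins, drop = FALSE]
  if (!is.null(mask)) vals[!mask[, bins, drop = FALSE]] <- NA
  epoch_swa <- rowMeans(vals, na.rm = TRUE)
  is_state <- hyp$state[seq_len(n_ep)] == state
  ep_per_int <- interval_s / spectra$epoch_s
  int_id <- (seq_len(n_ep) - 1) %/% ep_per_int
  fine <- do.call(rbind, lapply(unique(int_id), function(i) {
    sel <- int_id == i & is_state
    data.frame(t_start_s = i * interval_s,
               swa = if (any(sel)) mean(epoch_swa[sel]) else NA_real_,
               n_epochs = sum(sel))
  }))
  merged_id <- fine$t_start_s %/% (interval_s * merge_intervals)
  merged <- do.call(rbind, lapply(unique(merged_id), function(i) {
    sel <- merged_id == i & !is.na(fine$swa)
    data.frame(t_start_s = i * interval_s * merge_intervals,
               swa = if (any(sel)) mean(fine$swa[sel]) else NA_real_)
  }))
  list(fine = fine, merged = merged)
}

#' Automated vigilance-state scorer (surrogate)
#'
#' Scores each 4-s epoch as Wake when the EMG power exceeds a threshold
#' (by default placed between the two modes of the log EMG power
#' distribution, found by minimising within-class variance), and
#' otherwise as the sleep state whose defining band (NREM 0.5--4 Hz,
#' REM 4.5--8 Hz, REM2 8.5--20 Hz) has the highest relative power
#' (band power divided by band width). This is an explicit surrogate for
#' manual scoring, intended for synthetic-data testing.
#'
#' @param eeg numeric EEG signal (uV) used for the sleep-state bands.
#' @param emg numeric EMG signal (uV); required.
#' @param fs_hz sampling rate of both signals (256).
#' @param emg_threshold optional fixed EMG power threshold (uV^2);
#'   overrides the automatic split.
#' @return [hypnogram()] of scored states.
#' @export
score_epochs_auto <- function(eeg, emg, fs_hz = 256, emg_threshold = NULL) {
  if (is.null(emg)) stop("EMG signal required for wake scoring", call. = FALSE)
  spe <- EPOCH_LEN_S * fs_hz
  n_epochs <- floor(length(eeg) / spe)
  emg_pow <- vapply(seq_len(n_epochs), function(e) {
    mean(emg[((e - 1) * spe + 1):(e * spe)]^2)
  }, numeric(1))
  if (is.null(emg_threshold)) {
    emg_threshold <- exp(otsu_split(log(pmax(emg_pow, 1e-12))))
  }
  sp <- epoch_spectra(eeg, fs_hz)
  band_rel <- vapply(STATE_BANDS, function(b) {
    sel <- sp$freq_hz >= b[1] & sp$freq_hz <= b[2]
    rowSums(sp$power[, sel, drop = FALSE]) / (b[2] - b[1])
  }, numeric(n_epochs))
  if (is.null(dim(band_rel))) band_rel <- matrix(band_rel, nrow = 1)
  sleep_state <- names(STATE_BANDS)[max.col(band_rel, ties.method = "first")]
  hypnogram(ifelse(emg_pow > emg_threshold, "Wake", sleep_state))
}

# 1-D Otsu split: threshold minimising within-class variance
otsu_split <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  if (n < 2) return(max(x))
  best <- Inf; thr <- xs[1]
  for (k in seq_len(n - 1)) {
    v1 <- if (k > 1) stats::var(xs[1:k]) else 0
    v2 <- if (k < n - 1) stats::var(xs[(k + 1):n]) else 0
    w <- k * ifelse(is.na(v1), 0, v1) + (n - k) * ifelse(is.na(v2), 0, v2)
    if (w < best) { best <- w; thr <- (xs[k] + xs[k + 1]) / 2 }
  }
  thr
}
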