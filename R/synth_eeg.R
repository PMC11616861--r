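#' Ground truth for the EEG/EMG recording generator
#'
#' The generator emulates the statistical structure the sleep analysis
#' assumes: a semi-Markov hypnogram over \{Wake, NREM, REM, REM2\} with
#' geometric bout lengths on the 4-s epoch grid; EEG built from a broadband
#' pink-noise floor plus three band-limited noise processes (slow 0.5--4 Hz,
#' theta 4.5--8 Hz, high 8.5--20 Hz) whose amplitudes are stepped per epoch
#' according to the state, so that the scoring bands are separable; an EMG
#' channel with high power in Wake and low power in sleep; and a damped-
#' sinusoid evoked-potential template added at stimulus onsets with a
#' state-dependent gain and per-trial amplitude jitter.
#'
#' The EEG literature gives no quantitative amplitude ranges for ferret
#' state-specific EEG, so the default amplitudes are free parameters chosen
#' to give realistic-looking signals with clearly separable states (slow
#' waves of tens of microvolts, low-voltage wake EEG, evoked components of
#' the order of 100 microvolts); they are not estimates of any animal.
#'
#' @param duration_s recording duration in seconds; must be a multiple of 4.
#' @param fs_hz sampling rate (default 256).
#' @param mean_bout_epochs named numeric, mean bout duration (epochs) per
#'   state.
#' @param transition 4x4 row-stochastic matrix of between-state transition
#'   probabilities (zero diagonal), rows/cols Wake, NREM, REM, REM2.
#' @param state_band_amp 4x3 matrix (states x bands `slow`, `theta`,
#'   `high`) of band-noise amplitudes (uV SD).
#' @param pink_amp broadband pink-noise floor amplitude (uV SD).
#' @param emg_amp named numeric, EMG amplitude (uV SD) per state.
#' @param artefact_prob per-epoch probability of an artefact epoch.
#' @param artefact_amp amplitude (uV SD) of the broadband noise burst added
#'   in artefact epochs.
#' @param evoked_components data.frame of evoked-template components
#'   (`latency_s`, `amp_uv`, `freq_hz`, `decay_s`), frontal derivation.
#' @param occipital_gain scalar gain of the occipital evoked template
#'   relative to frontal.
#' @param evoked_state_gain named numeric, evoked amplitude scaling per
#'   state (>= 0).
#' @param evoked_jitter_sd SD of the multiplicative per-trial amplitude
#'   jitter (0 = none).
#' @param seed integer seed.
#' @return object of class `eeg_ground_truth`.
#' @export
eeg_ground_truth <- function(duration_s = 7200,
                             fs_hz = 256,
                             mean_bout_epochs = c(Wake = 30, NREM = 60,
                                                  REM = 20, REM2 = 18),
                             transition = default_transition(),
                             state_band_amp = default_state_band_amp(),
                             pink_amp = 5,
                             emg_amp = c(Wake = 30, NREM = 5, REM = 3,
                                         REM2 = 3),
                             artefact_prob = 0.01,
                             artefact_amp = 200,
                             evoked_components = data.frame(
                               latency_s = c(0.05, 0.15, 0.30),
                               amp_uv = c(300, 225, 150),
                               freq_hz = c(12, 8, 7),
                               decay_s = c(0.02, 0.04, 0.06)),
                             occipital_gain = 0.6,
                             evoked_state_gain = c(Wake = 1, NREM = 0.6,
                                                   REM = 0.75, REM2 = 0.9),
                             evoked_jitter_sd = 0.1,
                             seed = 1L) {
  if (duration_s %% EPOCH_LEN_S != 0) {
    stop("duration_s must be a multiple of 4 s", call. = FALSE)
  }
  states <- setdiff(VIGILANCE_STATES, "Artefact")
  stopifnot(identical(rownames(transition), states),
            identical(sort(names(mean_bout_epochs)), sort(states)),
            all(evoked_state_gain >= 0))
  stopifnot_prob(artefact_prob, "artefact_prob")
  if (any(abs(rowSums(transition) - 1) > 1e-8) || any(diag(transition) != 0)) {
    stop("transition must be row-stochastic with zero diagonal", call. = FALSE)
  }
  structure(list(duration_s = duration_s, fs_hz = fs_hz,
                 mean_bout_epochs = mean_bout_epochs, transition = transition,
                 state_band_amp = state_band_amp, pink_amp = pink_amp,
                 emg_amp = emg_amp, artefact_prob = artefact_prob,
                 artefact_amp = artefact_amp,
                 evoked_components = evoked_components,
                 occipital_gain = occipital_gain,
                 evoked_state_gain = evoked_state_gain,
                 evoked_jitter_sd = evoked_jitter_sd,
                 seed = as.integer(seed)),
            class = "eeg_ground_truth")
}

#' @rdname eeg_ground_truth
#' @export
default_transition <- function() {
  states <- c("Wake", "NREM", "REM", "REM2")
  m <- matrix(c(0.00, 0.90, 0.05, 0.05,
                0.30, 0.00, 0.38, 0.32,
                0.50, 0.45, 0.00, 0.05,
                0.50, 0.45, 0.05, 0.00),
              # Wake mostly enters NREM; NREM exits split between REM,
              # REM2 and brief awakenings; REM/REM2 mostly end in waking
              # or a return to NREM
              nrow = 4, byrow = TRUE, dimnames = list(states, states))
  m
}

#' @rdname eeg_ground_truth
#' @export
default_state_band_amp <- function() {
  matrix(c(4, 4, 5,     # Wake: low-voltage desynchronised
           27, 6, 4,    # NREM: slow-wave dominated
           5, 12, 4,    # REM: theta dominated
           4, 5, 15),   # REM2: high-frequency dominated
         nrow = 4, byrow = TRUE,
         dimnames = list(c("Wake", "NREM", "REM", "REM2"),
                         c("slow", "theta", "high")))
}

#' Construct a hypnogram
#'
#' @param states character vector of epoch labels from
#'   \{Wake, NREM, REM, REM2, Artefact\}.
#' @param epoch_s epoch length in seconds (4).
#' @param underlying optional character vector of the states underlying
#'   artefact-labelled epochs (generator ground truth).
#' @return data.frame of class `hypnogram` with columns `epoch_index`
#'   (0-based) and `state`.
#' @export
hypnogram <- function(states, epoch_s = EPOCH_LEN_S, underlying = NULL) {
  states <- as.character(states)
  bad <- setdiff(unique(states), VIGILANCE_STATES)
  if (length(bad)) {
    stop("unknown vigilance state label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  h <- data.frame(epoch_index = seq_along(states) - 1L, state = states,
                  stringsAsFactors = FALSE)
  attr(h, "epoch_s") <- epoch_s
  if (!is.null(underlying)) attr(h, "underlying_state") <- underlying
  class(h) <- c("hypnogram", "data.frame")
  h
}

# semi-Markov state sequence with geometric bout lengths
gen_hypnogram_states <- function(gt, n_epochs) {
  states <- rownames(gt$transition)
  seq_out <- character(0)
  st <- "Wake"
  while (length(seq_out) < n_epochs) {
    len <- 1L + rgeom(1L, 1 / gt$mean_bout_epochs[[st]])
    seq_out <- c(seq_out, rep(st, len))
    st <- sample(states, 1L, prob = gt$transition[st, ])
  }
  seq_out[seq_len(n_epochs)]
}

#' Build a stimulus presentation schedule
#'
#' Each frequency x level combination is presented `repetitions` times in
#' randomised order with inter-stimulus intervals drawn uniformly from
#' `isi_range_s`. Stimuli last 0.82 s with a central 38-ms silent gap, so
#' with the minimum 10-s interval events never overlap.
#'
#' @param freq_hz stimulus centre frequencies (Hz).
#' @param level_db stimulus levels (dB SPL).
#' @param repetitions presentations per combination (default 200).
#' @param isi_range_s inter-stimulus interval range (s), default \[10, 42\].
#' @param start_s onset of the first stimulus (s).
#' @param seed integer seed.
#' @return data.frame of class `stimulus_schedule` with `onset_s`,
#'   `freq_hz`, `level_db`; attributes `stim_dur_s` (0.82), `gap_s`
#'   (0.038) and `end_s` (offset of the last stimulus).
#' @export
stimulus_schedule <- function(freq_hz = c(1000, 4000, 8000, 16000),
                              level_db = c(40, 50, 60, 65),
                              repetitions = 200L,
                              isi_range_s = c(10, 42),
                              start_s = 30,
                              seed = 1L) {
  stopifnot(repetitions >= 1, isi_range_s[1] <= isi_range_s[2])
  set.seed(substream_seed(seed, "schedule"))
  combos <- expand.grid(freq_hz = freq_hz, level_db = level_db)
  idx <- sample(rep(seq_len(nrow(combos)), each = repetitions))
  n <- length(idx)
  isi <- runif(n - 1, isi_range_s[1], isi_range_s[2])
  onsets <- start_s + c(0, cumsum(isi))
  sch <- data.frame(onset_s = onsets,
                    freq_hz = combos$freq_hz[idx],
                    level_db = combos$level_db[idx])
  attr(sch, "stim_dur_s") <- 0.82
  attr(sch, "gap_s") <- 0.038
  attr(sch, "end_s") <- max(onsets) + 0.82
  class(sch) <- c("stimulus_schedule", "data.frame")
  sch
}

# pink (1/f power) noise of unit SD via FFT shaping; padded to a
# 5-smooth length so the FFT stays O(n log n) for awkward durations
pink_noise <- function(n, fs) {
  m <- stats::nextn(n, c(2, 3, 5))
  x <- rnorm(m)
  f <- c(0, seq_len(m - 1)) * fs / m
  f <- pmin(f, fs - f)          # fold to |f|
  h <- ifelse(f > 0, 1 / sqrt(pmax(f, fs / m)), 0)
  y <- Re(fft(fft(x) * h, inverse = TRUE))[seq_len(n)] / m
  y / sd(y)
}

# band-limited unit-SD noise (4th order Butterworth, single pass; phase
# is irrelevant for stationary noise)
band_noise <- function(n, fs, band) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  y <- signal::filter(bf, rnorm(n))
  y / sd(y)
}

#' Evoked-potential template (sum of damped sinusoids)
#'
#' @param t_s time (s) relative to stimulus onset.
#' @param components data.frame with `latency_s`, `amp_uv`, `freq_hz`,
#'   `decay_s`.
#' @return template amplitude (uV) at `t_s`.
#' @export
evoked_template <- function(t_s, components) {
  y <- numeric(length(t_s))
  for (i in seq_len(nrow(components))) {
    dt <- t_s - components$latency_s[i]
    on <- dt >= 0
    y[on] <- y[on] + components$amp_uv[i] * exp(-dt[on] / components$decay_s[i]) *
      cos(2 * pi * components$freq_hz[i] * dt[on])
  }
  y
}

#' Generate a synthetic EEG/EMG recording with hypnogram ground truth
#'
#' Produces frontal and occipital EEG and an EMG trace whose per-epoch
#' band composition follows a generated semi-Markov hypnogram. When a
#' stimulus schedule is supplied, the evoked template is added at each
#' onset, scaled by the state of the epoch containing the onset and by the
#' per-trial jitter. Artefact epochs receive a broadband noise burst and
#' are labelled `Artefact` in the hypnogram (the underlying state is kept
#' in the `underlying_state` attribute).
#'
#' @param gt [eeg_ground_truth()].
#' @param schedule optional [stimulus_schedule()]; must end before the
#'   recording does (with 2 s margin for the evoked tail).
#' @param channels which channels to synthesise (dropping unused channels
#'   saves time in simulation studies); default all three.
#' @return object of class `eeg_recording`: list with `signals` (named
#'   list `EEG-Frontal`, `EEG-Occipital`, `EMG`, uV), `fs_hz`,
#'   `hypnogram`, `schedule` (or NULL) and `ground_truth`.
#' @export
gen_eeg_recording <- function(gt, schedule = NULL,
                              channels = c("EEG-Frontal", "EEG-Occipital",
                                           "EMG")) {
  stopifnot(inherits(gt, "eeg_ground_truth"))
  if (!is.null(schedule) && attr(schedule, "end_s") + 2 > gt$duration_s) {
    stop("stimulus schedule extends past the end of the recording",
         call. = FALSE)
  }
  fs <- gt$fs_hz
  n_epochs <- gt$duration_s / EPOCH_LEN_S
  n <- gt$duration_s * fs
  spe <- EPOCH_LEN_S * fs              # samples per epoch

  set.seed(substream_seed(gt$seed, "hypnogram"))
  underlying <- gen_hypnogram_states(gt, n_epochs)
  artefact <- runif(n_epochs) < gt$artefact_prob
  labels <- ifelse(artefact, "Artefact", underlying)
  hyp <- hypnogram(labels, underlying = underlying)

  # per-epoch band gains expanded to sample resolution
  gain_for <- function(band) {
    rep(gt$state_band_amp[underlying, band], each = spe)
  }
  bands <- list(slow = STATE_BANDS$NREM, theta = STATE_BANDS$REM,
                high = STATE_BANDS$REM2)
  eeg <- list()
  for (deriv in intersect(c("EEG-Frontal", "EEG-Occipital"), channels)) {
    set.seed(substream_seed(gt$seed, paste0("eeg:", deriv)))
    x <- if (gt$pink_amp > 0) gt$pink_amp * pink_noise(n, fs) else numeric(n)
    for (b in names(bands)) {
      g <- gain_for(b)
      if (any(g > 0)) x <- x + g * band_noise(n, fs, bands[[b]])
    }
    eeg[[deriv]] <- x
  }
  signals <- eeg
  if ("EMG" %in% channels) {
    set.seed(substream_seed(gt$seed, "emg"))
    emg_gain <- rep(gt$emg_amp[underlying], each = spe)
    signals$EMG <- if (any(emg_gain > 0)) {
      emg_gain * band_noise(n, fs, c(10, 100))
    } else numeric(n)
  }

  if (any(artefact) && gt$artefact_amp > 0) {
    set.seed(substream_seed(gt$seed, "artefact"))
    for (e in which(artefact)) {
      idx <- ((e - 1) * spe + 1):(e * spe)
      burst <- rnorm(spe, 0, gt$artefact_amp)
      for (ch in names(signals)) {
        signals[[ch]][idx] <- signals[[ch]][idx] +
          if (ch == "EMG") rnorm(spe, 0, gt$artefact_amp) else burst
      }
    }
  }

  if (!is.null(schedule)) {
    set.seed(substream_seed(gt$seed, "evoked"))
    t_tpl <- seq(0, 1.5, by = 1 / fs)
    tpl <- list("EEG-Frontal" = evoked_template(t_tpl, gt$evoked_components))
    tpl[["EEG-Occipital"]] <- gt$occipital_gain * tpl[["EEG-Frontal"]]
    for (k in seq_len(nrow(schedule))) {
      onset <- schedule$onset_s[k]
      ep <- floor(onset / EPOCH_LEN_S) + 1L
      gain <- gt$evoked_state_gain[[underlying[ep]]]
      jit <- if (gt$evoked_jitter_sd > 0) {
        max(0, 1 + rnorm(1, 0, gt$evoked_jitter_sd))
      } else 1
      i0 <- round(onset * fs) + 1L
      idx <- i0:(i0 + length(t_tpl) - 1L)
      for (ch in intersect(names(tpl), names(signals))) {
        signals[[ch]][idx] <- signals[[ch]][idx] + gain * jit * tpl[[ch]]
      }
    }
  }

  structure(list(signals = signals, fs_hz = fs,
                 hypnogram = hyp, schedule = schedule, ground_truth = gt),
            class = "eeg_recording")
}
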