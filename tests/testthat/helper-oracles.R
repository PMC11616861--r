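# Brute-force counting oracles and small fixture builders used across tests.

# proportion-correct per cell by explicit loop (no aggregate/vapply tricks)
count_rate_oracle <- function(trials, by) {
  keys <- unique(trials[by])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- rep(TRUE, nrow(trials))
    for (col in by) sel <- sel & trials[[col]] == keys[[col]][i]
    n_ok <- 0; n <- 0
    for (j in which(sel)) {
      n <- n + 1
      if (trials$correct[j]) n_ok <- n_ok + 1
    }
    out[[i]] <- data.frame(keys[i, , drop = FALSE], n = n, rate = n_ok / n)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# hand-built gap trial rows
gap_trial_row <- function(session = "s1", stimulus = "BBN", gap_ms = 20,
                          correct = TRUE, rt_s = 1, correction = FALSE) {
  data.frame(session = session, animal = "F1", condition = "BL",
             stimulus = stimulus,
             trial_class = if (is.na(gap_ms)) "no-gap" else as.character(gap_ms),
             gap_ms = gap_ms, response_side = "left", correct = correct,
             rt_s = rt_s, correction = correction, stringsAsFactors = FALSE)
}

gap_trials_table <- function(...) {
  do.call(rbind, list(...))
}

# a session with n presentations of each of the seven gap lengths
full_session <- function(session = "s1", n_per_gap = 6, stimulus = "BBN") {
  do.call(rbind, lapply(tinsleep:::GAP_LENGTHS_MS, function(g) {
    do.call(rbind, replicate(n_per_gap, gap_trial_row(session, stimulus, g),
                             simplify = FALSE))
  }))
}

# hand-built silence trial rows
silence_trial_row <- function(session = "s1", class_group = "silence",
                              correct = TRUE, rt_s = 1) {
  data.frame(session = session, animal = "F1", condition = "BL",
             trial_class = class_group, class_group = class_group,
             response_side = "left", correct = correct, rt_s = rt_s,
             correction = FALSE, stringsAsFactors = FALSE)
}

silence_session <- function(session, n_nbn = 6, n_am = 6, n_sil = 6,
                            p_correct = 1) {
  rows <- c(replicate(n_nbn, "NBN"), replicate(n_am, "AM"),
            replicate(n_sil, "silence"))
  do.call(rbind, lapply(seq_along(rows), function(i) {
    silence_trial_row(session, rows[i], correct = (i %% round(1 / p_correct)
                                                   != 0) || p_correct == 1)
  }))
}

# noiseless EEG ground truth: evoked template only
quiet_eeg_gt <- function(duration_s, state_gain = c(Wake = 1, NREM = 0.6,
                                                    REM = 0.75, REM2 = 0.9),
                         seed = 1L, ...) {
  eeg_ground_truth(duration_s = duration_s,
                   state_band_amp = default_state_band_amp() * 0,
                   pink_amp = 0,
                   emg_amp = c(Wake = 0, NREM = 0, REM = 0, REM2 = 0),
                   artefact_prob = 0,
                   evoked_state_gain = state_gain,
                   evoked_jitter_sd = 0, seed = seed, ...)
}
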