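test_that("state percentages count non-artefact epochs and conserve 100%", {
  expect_equal(state_percentages(hypnogram(rep("Wake", 10)))$percent[["Wake"]],
               100)
  hyp <- hypnogram(c("Wake", "Wake", "NREM", "NREM", "NREM", "NREM",
                     "REM", "REM", "REM2", "REM2"))
  p <- state_percentages(hyp)
  expect_equal(p$percent, c(Wake = 20, NREM = 40, REM = 20, REM2 = 20))
  expect_equal(p$sleep_percent, 80)
  expect_equal(sum(p$percent), 100, tolerance = 1e-12)
  # artefacts excluded from the denominator, reported separately
  hyp2 <- hypnogram(c("Wake", "Artefact", "NREM", "NREM"))
  p2 <- state_percentages(hyp2)
  expect_equal(p2$percent[["Wake"]], 100 / 3, tolerance = 1e-12)
  expect_equal(p2$artefact_percent, 25)
  expect_error(state_percentages(hypnogram(rep("Artefact", 4))), "artefact")
})

test_that("episode detection counts runs and honours artefact bridging", {
  ep <- episodes(hypnogram(c("Wake", "Wake", "NREM", "NREM", "Wake")), "Wake")
  expect_equal(ep$count, 2)
  expect_equal(ep$episodes$duration_min * 60, c(8, 4))
  bridged <- episodes(hypnogram(c("Wake", "Artefact", "Wake")), "Wake",
                      bridge_artefacts = TRUE)
  split <- episodes(hypnogram(c("Wake", "Artefact", "Wake")), "Wake",
                    bridge_artefacts = FALSE)
  expect_equal(bridged$count, 1)
  expect_equal(split$count, 2)
  # bridged artefact epochs are not counted towards the duration
  expect_equal(bridged$episodes$n_epochs, 2)
  # episode durations partition total state time
  set.seed(5)
  states <- sample(c("Wake", "NREM", "REM", "Artefact"), 500, replace = TRUE)
  hyp <- hypnogram(states)
  for (st in c("Wake", "NREM")) {
    ep2 <- episodes(hyp, st)
    expect_equal(sum(ep2$episodes$n_epochs), sum(states == st))
  }
})

test_that("a pure on-grid tone concentrates in its main lobe with the peak bin
           at the tone frequency", {
  a <- 40
  t <- seq(1 / 256, 20 * 4, by = 1 / 256)
  sp <- epoch_spectra(a * sin(2 * pi * 2 * t), 256)
  i <- which(sp$freq_hz == 2)
  lobe <- rowSums(sp$power[, (i - 1):(i + 1)]) / rowSums(sp$power)
  expect_true(all(lobe >= 0.95))
  expect_true(all(apply(sp$power, 1, which.max) == i))
  # band power approximates the sine power A^2/2 (Parseval consistency)
  expect_equal(rowSums(sp$power)[1], a^2 / 2, tolerance = 1e-3)
  # zero signal -> zero power
  expect_true(all(epoch_spectra(numeric(256 * 8), 256)$power == 0))
})

test_that("white-noise spectra are flat across bins", {
  set.seed(31)
  sp <- epoch_spectra(rnorm(256 * 4 * 1000, sd = 5), 256)
  mu <- colMeans(sp$power)
  sel <- sp$freq_hz >= 1 & sp$freq_hz <= 30
  expect_lt(max(abs(mu[sel] / mean(mu[sel]) - 1)), 0.15)
})

test_that("outlier masking flags constructed outliers and nothing else", {
  # power-like values straight into the container: exponential per bin
  set.seed(8)
  n_ep <- 1000
  sp <- structure(list(power = matrix(stats::rexp(n_ep * 121), nrow = n_ep),
                       freq_hz = seq(0, 30, by = 0.25), epoch_s = 4),
                  class = "epoch_spectra")
  hyp <- hypnogram(rep("NREM", n_ep))
  # homogeneous data: the 600-SD rule masks nothing
  m0 <- bootstrap_outlier_mask(sp, hyp, "NREM", seed = 2)
  expect_true(all(m0))
  sp$power[77, 30] <- sp$power[77, 30] * 1e4
  m1 <- bootstrap_outlier_mask(sp, hyp, "NREM", seed = 2)
  expect_false(m1[77, 30])
  expect_equal(sum(!m1), 1)
  # masking decisions survive epoch reordering
  perm <- sample(n_ep)
  sp_p <- sp
  sp_p$power <- sp$power[perm, ]
  m2 <- bootstrap_outlier_mask(sp_p, hyp, "NREM", seed = 2)
  expect_false(m2[which(perm == 77), 30])
  expect_equal(sum(!m2), 1)
  # too few epochs of the state: all-valid with a warning
  hyp_few <- hypnogram(c(rep("REM", 5), rep("Wake", n_ep - 5)))
  expect_warning(m3 <- bootstrap_outlier_mask(sp, hyp_few, "REM", seed = 2),
                 "fewer than")
  expect_true(all(m3[1:5, ]))
  expect_true(all(is.na(m3[-(1:5), ])))
})

test_that("state spectra average valid epochs and merge into 0.5 Hz bins", {
  sp <- epoch_spectra(rnorm(256 * 4 * 50, sd = 5), 256)
  hyp <- hypnogram(rep("NREM", 50))
  # constant spectra -> zero SE
  spc <- sp
  spc$power <- matrix(2, nrow = 50, ncol = ncol(sp$power))
  s0 <- state_spectrum(spc, hyp, "NREM")
  expect_true(all(s0$se == 0))
  expect_true(all(s0$mean == 2))
  s1 <- state_spectrum(sp, hyp, "NREM")
  # each 0.5 Hz value is the mean of its two 0.25 Hz parents
  i <- which(s1$freq_hz == 1.0)
  expect_equal(s1$merged$mean[s1$merged$freq_hz == 1.0],
               mean(s1$mean[c(i - 1, i)]))
  expect_null(state_spectrum(sp, hyp, "REM2"))
})

test_that("the generated NREM spectrum peaks inside the slow-wave band", {
  egt <- eeg_ground_truth(duration_s = 1200, artefact_prob = 0, seed = 13)
  rec <- gen_eeg_recording(egt, channels = "EEG-Frontal")
  sp <- epoch_spectra(rec$signals[["EEG-Frontal"]], rec$fs_hz)
  s <- state_spectrum(sp, rec$hypnogram, "NREM")
  pk <- s$freq_hz[which.max(s$mean[s$freq_hz > 0])]
  expect_gte(pk, 0.5)
  expect_lte(pk, 4)
})

test_that("SWA time course averages NREM intervals and merges hours", {
  # constant power p in every bin -> SWA = p wherever NREM occurs
  n_ep <- 900   # one hour
  sp <- list(power = matrix(3, nrow = n_ep, ncol = 121),
             freq_hz = seq(0, 30, by = 0.25), epoch_s = 4)
  class(sp) <- "epoch_spectra"
  states <- rep("Wake", n_ep)
  states[1:100] <- "NREM"          # NREM only in the first 15-min interval
  tc <- swa_timecourse(sp, hypnogram(states))
  expect_equal(tc$fine$swa[1], 3)
  expect_true(all(is.na(tc$fine$swa[-1])))
  # merged hour = mean of available 15-min values
  expect_equal(tc$merged$swa[1], 3)
  states2 <- rep(c("NREM", "Wake"), n_ep / 2)
  tc2 <- swa_timecourse(sp, hypnogram(states2))
  expect_equal(tc2$merged$swa[1], mean(tc2$fine$swa))
})

test_that("SWA scales with the square of the slow-band amplitude", {
  amps <- default_state_band_amp()
  amps[, c("theta", "high")] <- 0
  mk <- function(mult) {
    a <- amps
    a[, "slow"] <- a[, "slow"] * mult
    gt <- eeg_ground_truth(duration_s = 1200, state_band_amp = a,
                           pink_amp = 0, artefact_prob = 0, seed = 19)
    rec <- gen_eeg_recording(gt, channels = "EEG-Frontal")
    sp <- epoch_spectra(rec$signals[["EEG-Frontal"]], rec$fs_hz)
    swa_timecourse(sp, rec$hypnogram)
  }
  r1 <- mk(1); r2 <- mk(2)
  # same seed, doubled amplitude: identical noise realisation, power x4
  expect_equal(r2$fine$swa, 4 * r1$fine$swa, tolerance = 1e-10)
})

test_that("the surrogate scorer labels canonical epochs correctly", {
  fs <- 256
  t <- seq(1 / fs, 8, by = 1 / fs)
  # high EMG -> Wake regardless of EEG content
  set.seed(3)
  emg_hi <- rnorm(length(t), sd = 50)
  eeg_sw <- 40 * sin(2 * pi * 2 * t)
  h1 <- score_epochs_auto(eeg_sw, emg_hi, fs, emg_threshold = 100)
  expect_true(all(h1$state == "Wake"))
  # 2 Hz EEG with quiet EMG -> NREM
  h2 <- score_epochs_auto(eeg_sw, rnorm(length(t), sd = 1), fs,
                          emg_threshold = 100)
  expect_true(all(h2$state == "NREM"))
  expect_error(score_epochs_auto(eeg_sw, NULL, fs), "EMG")
})

test_that("the surrogate scorer agrees with generator ground truth", {
  egt <- eeg_ground_truth(duration_s = 1200, seed = 23)
  rec <- gen_eeg_recording(egt)
  scored <- score_epochs_auto(rec$signals[["EEG-Frontal"]],
                              rec$signals$EMG, rec$fs_hz)
  truth <- attr(rec$hypnogram, "underlying_state")
  ok <- rec$hypnogram$state != "Artefact"
  expect_gte(mean(scored$state[ok] == truth[ok]), 0.9)
})
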