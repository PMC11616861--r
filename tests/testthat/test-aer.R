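test_that("trial extraction assigns states and drops artefact trials", {
  fs <- 256
  states <- c("Wake", "Wake", "NREM", "Artefact", "REM", "REM2",
              "NREM", "NREM", "Wake", "NREM")
  hyp <- hypnogram(states)
  eeg <- numeric(40 * fs)
  sch <- data.frame(onset_s = c(2, 6.5, 10, 13, 17, 21, 26, 33),
                    freq_hz = 4000, level_db = 60)
  attr(sch, "end_s") <- 34
  ev <- suppressWarnings(extract_trials(eeg, fs, sch, hyp,
                                        window_s = c(-0.5, 2)))
  # onset at 13 s sits in the artefact epoch (epoch 4: 12-16 s)
  expect_equal(ev$n_artefact_dropped, 1)
  # onset at 2 s lacks a 0.5 s pre-window? it has one; 33 s + 2 s is fine
  lookup <- states[floor(sch$onset_s / 4) + 1]
  expect_equal(ev$info$state, lookup[lookup != "Artefact"])
  expect_equal(nrow(ev$trials), 7)
  # an onset too close to the recording edge is dropped with a warning
  sch_edge <- data.frame(onset_s = c(2, 39.2), freq_hz = 4000, level_db = 60)
  expect_warning(ev2 <- extract_trials(eeg, fs, sch_edge, hyp,
                                       window_s = c(-0.5, 2)), "edge")
  expect_equal(nrow(ev2$trials), 1)
})

test_that("bootstrapped means are reproducible and converge to the group mean", {
  set.seed(44)
  base <- sin(seq(0, 2 * pi, length.out = 100))
  # identical trials -> every replicate equals the common trace
  same <- list(trials = matrix(rep(base, 10), nrow = 10, byrow = TRUE))
  bm <- bootstrap_group_means(same, n_boot = 20, seed = 3)
  expect_equal(bm, matrix(rep(base, 20), nrow = 20, byrow = TRUE))
  # determinism under seed
  noisy <- list(trials = matrix(rnorm(50 * 100), nrow = 50))
  expect_identical(bootstrap_group_means(noisy, n_boot = 20, seed = 9),
                   bootstrap_group_means(noisy, n_boot = 20, seed = 9))
  # mean of many bootstrapped means approaches the plain mean
  big <- bootstrap_group_means(noisy, n_boot = 1000, seed = 1)
  gm <- colMeans(noisy$trials)
  se <- apply(noisy$trials, 2, sd) / sqrt(50)
  expect_true(all(abs(colMeans(big) - gm) < 4 * se / sqrt(10)))
  expect_null(bootstrap_group_means(list(trials = NULL)))
})

test_that("moving-average smoothing matches its direct definition", {
  expect_equal(smooth_trace(rep(2, 30)), rep(2, 30))
  imp <- c(rep(0, 15), 1, rep(0, 15))
  sm <- smooth_trace(imp)
  expect_equal(sum(sm > 0), 8)
  expect_true(all(abs(sm[sm > 0] - 1 / 8) < 1e-12))
  # brute-force windowed mean on a ramp
  x <- seq_len(20) * 1.5
  direct <- vapply(seq_len(20), function(i) {
    lo <- max(i - 3, 1); hi <- min(i + 4, 20)
    mean(x[lo:hi])
  }, numeric(1))
  expect_equal(smooth_trace(x), direct)
  expect_error(smooth_trace(1:5), "shorter")
})

test_that("component magnitudes are max minus the subsequent minimum", {
  t_s <- seq(0, 1, by = 1 / 128)
  tr <- 10 * exp(-t_s / 0.2) * cos(2 * pi * 5 * (t_s - 0.1))
  win <- data.frame(component = "R1", start_s = 0.05, end_s = 0.35)
  mg <- component_magnitudes(tr, t_s, win)
  sel <- t_s >= 0.05 & t_s <= 0.35
  seg <- tr[sel]
  i <- which.max(seg)
  expect_equal(mg$magnitude, seg[i] - min(seg[(i + 1):length(seg)]))
  expect_gte(mg$magnitude, 0)
  # constructed peak/trough pair: 10 then -5 -> magnitude 15
  tr2 <- c(0, 2, 10, 3, -5, -1, 0, 0)
  mg2 <- component_magnitudes(tr2, seq_len(8), data.frame(
    component = "R1", start_s = 1, end_s = 8))
  expect_equal(mg2$magnitude, 15)
  # monotonically increasing segment has no subsequent minimum
  mg3 <- component_magnitudes(seq_len(20), seq_len(20), data.frame(
    component = "R1", start_s = 5, end_s = 10))
  expect_true(is.na(mg3$magnitude))
  expect_error(component_magnitudes(tr2, seq_len(8), data.frame(
    component = "R1", start_s = 20, end_s = 30)), "no samples")
})

test_that("component windows bracket the template latencies without overlap", {
  fs <- 128
  t_s <- seq(-0.5, 2, by = 1 / fs)
  comp <- eeg_ground_truth(duration_s = 400)$evoked_components
  tr <- evoked_template(t_s, comp)
  win <- derive_component_windows(tr, t_s)
  expect_equal(nrow(win), 3)
  for (i in 1:3) {
    expect_gte(comp$latency_s[i], win$start_s[i] - 0.02)
    expect_lte(comp$latency_s[i], win$end_s[i])
  }
  # windows are ordered and non-overlapping
  expect_true(all(win$start_s[-1] >= win$end_s[-3] - 1e-12))
  # a flat trace yields zero components
  expect_equal(nrow(derive_component_windows(numeric(321), t_s)), 0)
})

test_that("pooled magnitudes reduce to means and SEMs of the replicates", {
  tab <- data.frame(state = c("Wake", "Wake", "Wake", "NREM"),
                    magnitude = c(1, 2, 3, 5))
  class(tab) <- c("magnitude_table", "data.frame")
  p <- pool_magnitudes(tab, by = "state")
  w <- p[p$state == "Wake", ]
  expect_equal(w$mean, 2)
  expect_equal(w$sem, 1 / sqrt(3))
  n <- p[p$state == "NREM", ]
  expect_equal(n$mean, 5)
  expect_equal(n$sem, 0)
  # pooling over the flattened set equals pooling in stages
  tab$component <- c("R1", "R2", "R1", "R1")
  joint <- pool_magnitudes(tab, by = "state")
  expect_equal(joint$mean[joint$state == "Wake"], 2)
})

test_that("bootstrap dispersion shrinks with group size", {
  set.seed(6)
  mk_disp <- function(n) {
    trials <- matrix(rnorm(n * 64), nrow = n)
    bm <- bootstrap_group_means(list(trials = trials), n_boot = 200, seed = 4)
    mean(apply(bm, 2, sd))
  }
  d10 <- mk_disp(10)
  d90 <- mk_disp(90)
  expect_lt(d90, d10 / 2)   # roughly 1/3 expected for 9x the trials
})

test_that("state-scaled noiseless templates yield exactly proportional
           magnitudes end-to-end", {
  sch <- stimulus_schedule(freq_hz = 4000, level_db = 60, repetitions = 25,
                           isi_range_s = c(10, 12), seed = 14)
  dur <- ceiling((attr(sch, "end_s") + 10) / 4) * 4
  gt <- quiet_eeg_gt(dur, seed = 14)
  rec <- gen_eeg_recording(gt, schedule = sch, channels = "EEG-Frontal")
  ev <- extract_trials(rec$signals[["EEG-Frontal"]], rec$fs_hz, sch,
                       rec$hypnogram)
  win <- derive_component_windows(colMeans(ev$trials), ev$t_s)
  mt <- magnitude_table(ev, win, n_boot = 5, seed = 14)
  pooled <- pool_magnitudes(mt, by = "state")
  # per-state magnitude divided by the configured gain is state-invariant
  gains <- gt$evoked_state_gain[pooled$state]
  ratio <- pooled$mean / gains
  expect_lt(max(ratio) - min(ratio), 1e-9)
  # replicates of identical trials are identical within state x component
  per_comp <- pool_magnitudes(mt, by = c("state", "component"))
  expect_true(all(per_comp$sem < 1e-9))
  # and the magnitudes equal those measured on the pure template
  tpl <- evoked_template(ev$t_s, gt$evoked_components)
  truth <- component_magnitudes(smooth_trace(tpl), ev$t_s, win)
  wake <- mt[mt$state == "Wake" & mt$replicate == 1, ]
  expect_equal(wake$magnitude[order(wake$component)],
               truth$magnitude[order(truth$component)], tolerance = 1e-9)
})
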