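test_that("trial filtering removes corrections and slow responses", {
  tab <- gap_trials_table(
    gap_trial_row(correction = TRUE),
    gap_trial_row(rt_s = 4.9),
    gap_trial_row(rt_s = 5.0),
    gap_trial_row(rt_s = 5.1)
  )
  out <- filter_gap_trials(tab)
  # correction trial and the 5.1 s trial go; the boundary 5.0 s stays
  expect_equal(nrow(out), 2)
  expect_equal(sort(out$rt_s), c(4.9, 5.0))
  expect_equal(attr(out, "removed")[["correction"]], 1)
  expect_equal(attr(out, "removed")[["slow_rt"]], 1)
  # idempotent
  expect_equal(nrow(filter_gap_trials(out)), 2)
  # identity on clean tables
  clean <- gap_trials_table(gap_trial_row(), gap_trial_row(gap_ms = 50))
  expect_equal(nrow(filter_gap_trials(clean)), 2)
})

test_that("sparse sessions are dropped by the more-than-5 rule", {
  # 6 of 7 gap lengths with 4 presentations -> dropped
  sparse <- rbind(full_session("sA", n_per_gap = 4),
                  do.call(rbind, replicate(2, gap_trial_row("sA", gap_ms = 3),
                                           simplify = FALSE)))
  expect_equal(nrow(filter_gap_sessions(sparse)), 0)
  expect_equal(attr(filter_gap_sessions(sparse), "dropped_sessions"), "sA")
  # every gap length >= 5 presentations -> retained
  good <- full_session("sB", n_per_gap = 5)
  expect_equal(nrow(filter_gap_sessions(good)), nrow(good))
  # exactly 5 sparse gap lengths -> retained (strict "more than 5")
  five_sparse <- rbind(full_session("sC", n_per_gap = 4),
                       full_session("sC", n_per_gap = 4)[1:(2 * 4), ])
  counts <- table(five_sparse$gap_ms)
  expect_equal(sum(counts < 5), 5)
  expect_equal(nrow(filter_gap_sessions(five_sparse)), nrow(five_sparse))
})

test_that("hit and false-alarm rates equal the counting oracle", {
  set.seed(7)
  tab <- do.call(rbind, lapply(1:20, function(i) {
    gap_trial_row(session = sample(c("s1", "s2"), 1),
                  gap_ms = sample(c(NA, 10, 50), 1),
                  correct = runif(1) < 0.6)
  }))
  r <- hit_and_fa_rates(tab)
  gap <- tab[!is.na(tab$gap_ms), ]
  oracle <- count_rate_oracle(gap, c("session", "gap_ms"))
  for (i in seq_len(nrow(oracle))) {
    got <- r$hits$hit_rate[r$hits$session == oracle$session[i] &
                           r$hits$gap_ms == oracle$gap_ms[i]]
    expect_equal(got, oracle$rate[i])
  }
  nogap <- tab[is.na(tab$gap_ms), ]
  fa_oracle <- count_rate_oracle(nogap, "session")
  for (i in seq_len(nrow(fa_oracle))) {
    got <- r$fa$fa_rate[r$fa$session == fa_oracle$session[i]]
    expect_equal(got, 1 - fa_oracle$rate[i])
  }
})

test_that("psychometric fit recovers noiseless logistic rates", {
  gaps <- tinsleep:::GAP_LENGTHS_MS
  rates <- data.frame(gap_ms = gaps,
                      hit_rate = psychometric_fun(gaps, 10, 2.5, 0, 0))
  f <- fit_psychometric(rates, stimulus = "BBN")
  expect_true(f$converged)
  expect_false(f$not_crossing)
  expect_lt(abs(f$threshold_ms - 10), 0.05)
  expect_gt(f$slope_at_threshold, 0)
})

test_that("flat hit rates yield a not-crossing flag", {
  gaps <- tinsleep:::GAP_LENGTHS_MS
  f <- fit_psychometric(data.frame(gap_ms = gaps, hit_rate = rep(0.9, 7)),
                        stimulus = "BBN")
  expect_true(f$not_crossing)
  expect_true(is.na(f$threshold_ms))
  expect_false(f$included)
})

test_that("slope exclusion uses ten times the median across fits", {
  mk <- function(slopes) {
    data.frame(animal = "F1", stimulus = paste0("s", seq_along(slopes)),
               condition = "BL", slope_at_threshold = slopes,
               included = TRUE, reason = "", stringsAsFactors = FALSE)
  }
  out <- apply_slope_exclusion(mk(c(1, 1, 1, 1, 20)))
  expect_equal(out$included, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  out2 <- apply_slope_exclusion(mk(rep(2, 5)))
  expect_true(all(out2$included))
  # median 3.5 -> cut-off 35 -> both 100 and 120 excluded
  out3 <- apply_slope_exclusion(mk(c(1, 2, 3, 4, 100, 120)))
  expect_equal(sum(!out3$included), 2)
  expect_warning(apply_slope_exclusion(mk(1)), "no exclusion")
})

test_that("threshold normalisation reproduces the seven-step scale", {
  got <- normalize_threshold(c(3, 5, 10, 20, 50, 100, 270), method = "snap")
  expect_equal(got, 100 * (1 - 0:6 / 7))
  # interpolation agrees at the anchors and is monotone between them
  interp <- normalize_threshold(c(3, 5, 10, 20, 50, 100, 270))
  expect_equal(interp, got)
  mid <- normalize_threshold(c(4, 7, 15, 150))
  expect_true(all(diff(mid) < 0))
  expect_error(normalize_threshold(300), "270")
  expect_error(normalize_threshold(1), "270")
})

test_that("silence scoring applies the class-minimum and RT rules", {
  # a session with only 4 silence trials is excluded entirely
  s_bad <- silence_session("x1", n_nbn = 6, n_am = 6, n_sil = 4)
  s_good <- silence_session("x2", n_nbn = 6, n_am = 6, n_sil = 6)
  sc <- score_silence_sessions(rbind(s_bad, s_good))
  expect_equal(sc$sessions_excluded, "x1")
  expect_equal(sc$scores$prop_correct, rep(1, 3))
  # RT > 20 s trials are removed before session counting
  slow <- silence_session("x3", n_nbn = 6, n_am = 6, n_sil = 6)
  slow$rt_s[slow$class_group == "silence"][1:2] <- 25
  sc2 <- score_silence_sessions(slow)
  expect_equal(sc2$sessions_excluded, "x3")
  # all sessions excluded -> empty-result, not an error
  expect_equal(length(sc2$sessions_retained), 0)
})

test_that("silence scores equal brute-force counting on a toy table", {
  set.seed(12)
  tab <- do.call(rbind, lapply(1:30, function(i) {
    silence_trial_row("s1", sample(c("NBN", "AM", "silence"), 1),
                      correct = runif(1) < 0.7)
  }))
  # pad so every class has >= 5 trials
  tab <- rbind(tab, silence_session("s1", 5, 5, 5))
  sc <- score_silence_sessions(tab)
  oracle <- count_rate_oracle(tab, "class_group")
  for (i in seq_len(nrow(oracle))) {
    got <- sc$scores$prop_correct[sc$scores$class_group ==
                                  oracle$class_group[i]]
    expect_equal(got, oracle$rate[i])
  }
})

test_that("hit rate is non-decreasing in gap length for monotone truth", {
  for (th in c(5, 20, 100)) {
    p <- psychometric_fun(tinsleep:::GAP_LENGTHS_MS, th, 2.5, 0.05, 0.05)
    expect_true(all(diff(p) > 0))
    expect_true(all(p >= 0 & p <= 1))
  }
})
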