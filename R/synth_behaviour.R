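#' Ground truth for the behavioural generators
#'
#' Bundles the parameters of the simulated animal for the two operant
#' paradigms: a four-parameter logistic psychometric function per stimulus
#' for silent-gap detection (guess and lapse rates, threshold and slope on
#' the log-gap axis), the probability of a correct response on no-gap
#' trials, per-class correct probabilities for the silence-detection task,
#' and a lognormal response-time model.
#'
#' The `threshold_ms` parameter is the gap length at which the psychometric
#' function crosses a hit rate of 0.5, i.e. the quantity the analysis
#' module estimates; the logistic midpoint is derived from it.
#'
#' @param threshold_ms named numeric, true gap-detection threshold (ms) per
#'   stimulus; names are the stimulus labels. Must lie in \[3, 270\].
#' @param slope logistic slope on the log-gap axis (dimensionless).
#' @param guess,lapse lower/upper asymptote offsets of the psychometric
#'   function, both in \[0, 1\].
#' @param nogap_correct probability of a correct response on no-gap trials
#'   (1 minus the false-alarm rate).
#' @param silence_correct named numeric, probability correct per
#'   silence-task class; names `NBN`, `AM`, `silence`.
#' @param silence_class_probs trial-class mixture for the silence task;
#'   defaults to the paradigm proportions 50% NBN, 30% AM, 20% silence.
#' @param rt_meanlog,rt_sdlog lognormal response-time parameters (seconds).
#' @param rt_slow_prob probability that a trial instead draws a long
#'   response time (uniform on `rt_slow_range`), emulating disengaged
#'   trials that the session filters must remove.
#' @param rt_slow_range two-element range (s) for slow response times.
#' @param correction_trials logical; if `TRUE`, every incorrect response is
#'   followed by one flagged correction trial of the same class.
#' @param seed integer seed; the same seed reproduces the same tables.
#' @return object of class `behaviour_ground_truth`.
#' @export
behaviour_ground_truth <- function(threshold_ms = c("1kHz" = 20, "4kHz" = 20,
                                                    "8kHz" = 20, "16kHz" = 20,
                                                    "BBN" = 20),
                                   slope = 2.5,
                                   guess = 0.05,
                                   lapse = 0.05,
                                   nogap_correct = 0.9,
                                   silence_correct = c(NBN = 0.85, AM = 0.9,
                                                       silence = 0.8),
                                   silence_class_probs = c(NBN = 0.5, AM = 0.3,
                                                           silence = 0.2),
                                   rt_meanlog = log(1.5),
                                   rt_sdlog = 0.5,
                                   rt_slow_prob = 0.02,
                                   rt_slow_range = c(5.5, 12),
                                   correction_trials = TRUE,
                                   seed = 1L) {
  if (any(threshold_ms < 3) || any(threshold_ms > 270)) {
    stop("gap thresholds must lie within [3, 270] ms", call. = FALSE)
  }
  stopifnot_prob(c(guess, lapse, nogap_correct), "probabilities")
  stopifnot_prob(silence_correct, "silence_correct")
  if (abs(sum(silence_class_probs) - 1) > 1e-8) {
    stop("silence_class_probs must sum to 1", call. = FALSE)
  }
  if (guess >= 0.5 || lapse >= 0.5) {
    stop("guess and lapse must leave the 0.5 crossing reachable", call. = FALSE)
  }
  if (is.null(names(threshold_ms))) {
    names(threshold_ms) <- paste0("stim", seq_along(threshold_ms))
  }
  structure(list(threshold_ms = threshold_ms, slope = slope, guess = guess,
                 lapse = lapse, nogap_correct = nogap_correct,
                 silence_correct = silence_correct,
                 silence_class_probs = silence_class_probs,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
                 rt_slow_prob = rt_slow_prob, rt_slow_range = rt_slow_range,
                 correction_trials = correction_trials,
                 seed = as.integer(seed)),
            class = "behaviour_ground_truth")
}

#' Four-parameter logistic psychometric function on the log-gap axis
#'
#' `p(g) = guess + (1 - guess - lapse) / (1 + exp(-slope (log g - m)))`.
#'
#' @param gap_ms gap length(s) in ms.
#' @param threshold_ms gap length at which the function crosses 0.5.
#' @param slope logistic slope on the log-gap axis.
#' @param guess,lapse asymptote offsets.
#' @return hit probability in \[0, 1\].
#' @export
psychometric_fun <- function(gap_ms, threshold_ms, slope, guess = 0, lapse = 0) {
  m <- psychometric_midpoint(threshold_ms, slope, guess, lapse)
  guess + (1 - guess - lapse) * stats::plogis(slope * (log(gap_ms) - m))
}

# log-gap midpoint such that the function crosses 0.5 at threshold_ms
psychometric_midpoint <- function(threshold_ms, slope, guess, lapse) {
  l <- (0.5 - guess) / (1 - guess - lapse)
  if (any(l <= 0) || any(l >= 1)) {
    stop("0.5 is outside the reachable range of the psychometric function",
         call. = FALSE)
  }
  log(threshold_ms) - stats::qlogis(l) / slope
}

# response-time draw shared by the two paradigms
draw_rts <- function(n, gt) {
  rt <- rlnorm(n, gt$rt_meanlog, gt$rt_sdlog)
  slow <- runif(n) < gt$rt_slow_prob
  rt[slow] <- runif(sum(slow), gt$rt_slow_range[1], gt$rt_slow_range[2])
  rt
}

#' Generate silent-gap detection trial tables
#'
#' Simulates operant gap-detection sessions: within a session the stimulus
#' is fixed (stimuli rotate across sessions), gap and no-gap trials are
#' balanced, gap lengths are drawn uniformly from the seven-step set
#' \{3, 5, 10, 20, 50, 100, 270\} ms, and the correct flag is Bernoulli with
#' probability given by the animal's psychometric function (gap trials) or
#' `nogap_correct` (no-gap trials). Incorrect responses optionally trigger
#' one flagged correction trial. The ground truth is attached as the
#' `ground_truth` attribute.
#'
#' @param gt [behaviour_ground_truth()].
#' @param n_sessions number of sessions (>= 1); stimuli rotate across them.
#' @param trials_per_session non-correction trials per session (gap/no-gap
#'   balanced, so made even).
#' @param animal,condition labels copied into the table.
#' @return data.frame with one row per trial: `session`, `animal`,
#'   `condition`, `stimulus`, `trial_class`, `gap_ms`, `response_side`,
#'   `correct`, `rt_s`, `correction`.
#' @export
gen_gap_trials <- function(gt, n_sessions = 10L, trials_per_session = 100L,
                           animal = "F1", condition = "BL") {
  stopifnot(inherits(gt, "behaviour_ground_truth"), n_sessions >= 1)
  set.seed(substream_seed(gt$seed, paste0("gap_trials:", animal, condition)))
  n_half <- floor(trials_per_session / 2)
  stimuli <- names(gt$threshold_ms)
  out <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    stim <- stimuli[((s - 1L) %% length(stimuli)) + 1L]
    gap_ms <- c(sample(GAP_LENGTHS_MS, n_half, replace = TRUE),
                rep(NA_real_, n_half))
    ord <- sample.int(2L * n_half)
    gap_ms <- gap_ms[ord]
    is_gap <- !is.na(gap_ms)
    p <- ifelse(is_gap,
                psychometric_fun(ifelse(is_gap, gap_ms, 3), gt$threshold_ms[stim],
                                 gt$slope, gt$guess, gt$lapse),
                gt$nogap_correct)
    correct <- runif(length(p)) < p
    df <- data.frame(
      session = sprintf("%s-%s-s%02d", animal, condition, s),
      animal = animal, condition = condition, stimulus = stim,
      trial_class = ifelse(is_gap, as.character(gap_ms), "no-gap"),
      gap_ms = gap_ms,
      response_side = ifelse(is_gap == correct, "left", "right"),
      correct = correct,
      rt_s = draw_rts(length(p), gt),
      correction = FALSE,
      stringsAsFactors = FALSE
    )
    if (gt$correction_trials && any(!correct)) {
      corr <- df[!df$correct, , drop = FALSE]
      p2 <- p[!df$correct]
      corr$correct <- runif(nrow(corr)) < p2
      corr$rt_s <- draw_rts(nrow(corr), gt)
      corr$correction <- TRUE
      df <- rbind(df, corr)
    }
    out[[s]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "ground_truth") <- gt
  res
}

#' Generate silence-detection trial tables
#'
#' Simulates the three-class silence-detection paradigm: trial classes are
#' drawn with the paradigm proportions (50% NBN split over the four centre
#' frequencies, 30% AM, 20% silence); AM and silence trials are rewarded at
#' the +30 degree sensor and NBN at the -30 degree sensor; the correct flag
#' is Bernoulli per class.
#'
#' @inheritParams gen_gap_trials
#' @return data.frame with `session`, `animal`, `condition`, `trial_class`
#'   (`NBN-1kHz` ... `NBN-16kHz`, `AM`, `silence`), `class_group`,
#'   `response_side`, `correct`, `rt_s`, `correction`.
#' @export
gen_silence_trials <- function(gt, n_sessions = 10L, trials_per_session = 100L,
                               animal = "F1", condition = "BL") {
  stopifnot(inherits(gt, "behaviour_ground_truth"), n_sessions >= 1)
  set.seed(substream_seed(gt$seed, paste0("silence_trials:", animal, condition)))
  nbn <- paste0("NBN-", c("1kHz", "4kHz", "8kHz", "16kHz"))
  classes <- c(nbn, "AM", "silence")
  probs <- c(rep(gt$silence_class_probs[["NBN"]] / 4, 4),
             gt$silence_class_probs[["AM"]], gt$silence_class_probs[["silence"]])
  out <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    cls <- sample(classes, trials_per_session, replace = TRUE, prob = probs)
    grp <- ifelse(startsWith(cls, "NBN"), "NBN", cls)
    p <- gt$silence_correct[grp]
    correct <- runif(length(p)) < p
    correct_side <- ifelse(grp == "NBN", "right", "left")
    out[[s]] <- data.frame(
      session = sprintf("%s-%s-sil%02d", animal, condition, s),
      animal = animal, condition = condition,
      trial_class = cls, class_group = grp,
      response_side = ifelse(correct, correct_side,
                             ifelse(correct_side == "left", "right", "left")),
      correct = correct,
      rt_s = draw_rts(length(p), gt),
      correction = FALSE,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "ground_truth") <- gt
  res
}
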