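#' Filter silent-gap detection trials
#'
#' Removes correction trials and trials with response times above the
#' 5-second cutoff (strictly greater than; a trial at exactly 5 s is
#' retained). Idempotent.
#'
#' @param trials gap-detection trial table (see [gen_gap_trials()]).
#' @param rt_cutoff_s response-time cutoff in seconds (default 5).
#' @return filtered table; the numbers of removed correction and slow
#'   trials are attached as the `removed` attribute.
#' @export
filter_gap_trials <- function(trials, rt_cutoff_s = 5) {
  n_corr <- sum(trials$correction)
  keep <- !trials$correction & trials$rt_s <= rt_cutoff_s
  out <- trials[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(correction = n_corr,
                            slow_rt = nrow(trials) - n_corr - nrow(out))
  attr(out, "ground_truth") <- attr(trials, "ground_truth")
  out
}

#' Filter sparse gap-detection sessions
#'
#' A session is dropped iff more than 5 of the gap lengths have fewer than
#' 5 presentations in that session (exactly 5 sparse gap lengths is
#' retained, reading the rule strictly).
#'
#' @param trials filtered gap-detection trial table.
#' @param min_presentations,max_sparse rule parameters (defaults 5 and 5).
#' @return table with sparse sessions removed; dropped session ids in the
#'   `dropped_sessions` attribute.
#' @export
filter_gap_sessions <- function(trials, min_presentations = 5,
                                max_sparse = 5) {
  keep_session <- vapply(split(trials, trials$session), function(df) {
    counts <- table(factor(df$gap_ms[!is.na(df$gap_ms)],
                           levels = GAP_LENGTHS_MS))
    sum(counts < min_presentations) <= max_sparse
  }, logical(1))
  dropped <- names(keep_session)[!keep_session]
  out <- trials[!(trials$session %in% dropped), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_sessions") <- dropped
  attr(out, "ground_truth") <- attr(trials, "ground_truth")
  out
}

#' Per-session hit and false-alarm rates
#'
#' Hit rate is the proportion of correct responses on gap trials, per
#' session x stimulus x gap length; the false-alarm rate is 1 minus the
#' proportion correct on no-gap trials, per session x stimulus. Cells with
#' no trials are absent from the output (downstream averaging is over
#' sessions that contribute).
#'
#' @param trials filtered gap-detection trial table.
#' @return list with `hits` (data.frame `session`, `stimulus`, `gap_ms`,
#'   `n`, `hit_rate`) and `fa` (data.frame `session`, `stimulus`, `n`,
#'   `fa_rate`, `nogap_correct`).
#' @export
hit_and_fa_rates <- function(trials) {
  gap <- trials[!is.na(trials$gap_ms), , drop = FALSE]
  nogap <- trials[is.na(trials$gap_ms), , drop = FALSE]
  hits <- aggregate(correct ~ session + stimulus + gap_ms, data = gap,
                    FUN = function(x) c(n = length(x), rate = mean(x)))
  hits <- data.frame(hits[c("session", "stimulus", "gap_ms")],
                     n = hits$correct[, "n"], hit_rate = hits$correct[, "rate"])
  fa <- aggregate(correct ~ session + stimulus, data = nogap,
                  FUN = function(x) c(n = length(x), rate = mean(x)))
  fa <- data.frame(fa[c("session", "stimulus")], n = fa$correct[, "n"],
                   nogap_correct = fa$correct[, "rate"],
                   fa_rate = 1 - fa$correct[, "rate"])
  list(hits = hits, fa = fa)
}

# mean-across-sessions hit rate per gap length for one stimulus
session_mean_hit_rates <- function(hits, stimulus) {
  h <- hits[hits$stimulus == stimulus, , drop = FALSE]
  if (!nrow(h)) return(data.frame(gap_ms = numeric(0), hit_rate = numeric(0)))
  agg <- aggregate(hit_rate ~ gap_ms, data = h, FUN = mean)
  agg[order(agg$gap_ms), ]
}

#' Fit a four-parameter sigmoid psychometric function
#'
#' Least-squares fit of `lo + (hi - lo) / (1 + exp(-b (log g - m)))` to the
#' session-averaged hit rate versus gap length, per animal x stimulus x
#' condition. The threshold is the gap length whose fitted hit rate is in
#' closest proximity to 0.5, found by dense evaluation over \[3, 270\] ms
#' (0.01-ms steps below 10 ms, 0.1-ms steps above; ties broken toward the
#' shorter gap). The slope at threshold is the analytic derivative of the
#' fitted function with respect to gap length in ms. If the fitted curve
#' does not cross 0.5 anywhere on \[3, 270\] ms the fit is flagged
#' `not_crossing` and the threshold is `NA`.
#'
#' @param rates output of [hit_and_fa_rates()], or a data.frame with
#'   columns `gap_ms` and `hit_rate` (already session-averaged).
#' @param animal,stimulus,condition labels for the fit record; `stimulus`
#'   selects rows when `rates` comes from [hit_and_fa_rates()].
#' @return one-row data.frame of class `psychometric_fit`: asymptotes
#'   `lo`, `hi`, log-gap midpoint `m`, slope `b`, `threshold_ms`,
#'   `slope_at_threshold` (hit rate per ms), flags `not_crossing`,
#'   `converged`, `included`, `reason`, and `n_gaps`.
#' @export
fit_psychometric <- function(rates, animal = "F1", stimulus = NULL,
                             condition = "BL") {
  if (is.list(rates) && !is.null(rates$hits)) {
    stopifnot(!is.null(stimulus))
    df <- session_mean_hit_rates(rates$hits, stimulus)
  } else {
    df <- rates[order(rates$gap_ms), c("gap_ms", "hit_rate")]
  }
  stimulus <- stimulus %||% "?"
  rec <- data.frame(animal = animal, stimulus = stimulus,
                    condition = condition, lo = NA_real_, hi = NA_real_,
                    m = NA_real_, b = NA_real_, threshold_ms = NA_real_,
                    slope_at_threshold = NA_real_, not_crossing = FALSE,
                    converged = FALSE, included = TRUE, reason = "",
                    n_gaps = nrow(df), stringsAsFactors = FALSE)
  class(rec) <- c("psychometric_fit", "data.frame")
  if (nrow(df) < 4) {
    rec$included <- FALSE
    rec$reason <- "fewer than 4 gap lengths with defined hit rates"
    return(rec)
  }
  lg <- log(df$gap_ms)
  y <- df$hit_rate
  if (diff(range(y)) < 1e-8) {
    # constant hit rate: the flat curve either never reaches 0.5 or is 0.5
    # everywhere (in which case the shortest gap is closest by the tie rule)
    rec[c("lo", "hi")] <- y[1]
    rec$converged <- TRUE
    rec$slope_at_threshold <- 0
    if (abs(y[1] - 0.5) < 1e-8) {
      rec$threshold_ms <- 3
    } else {
      rec$not_crossing <- TRUE
      rec$included <- FALSE
      rec$reason <- "fitted curve does not cross 0.5"
    }
    return(rec)
  }
  start <- list(lo = max(min(y), 0.001), hi = min(max(y), 0.999),
                m = lg[which.min(abs(y - (min(y) + max(y)) / 2))], b = 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ lo + (hi - lo) / (1 + exp(-b * (lg - m))),
                      start = start,
                      lower = c(lo = 0, hi = 0, m = log(0.5), b = 0.01),
                      upper = c(lo = 1, hi = 1, m = log(2000), b = 50),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    rec$included <- FALSE
    rec$reason <- paste("fit failed:", conditionMessage(fit))
    return(rec)
  }
  p <- as.list(stats::coef(fit))
  rec[c("lo", "hi", "m", "b")] <- p[c("lo", "hi", "m", "b")]
  rec$converged <- TRUE
  grid <- c(seq(3, 10, by = 0.01), seq(10.1, 270, by = 0.1))
  fval <- p$lo + (p$hi - p$lo) / (1 + exp(-p$b * (log(grid) - p$m)))
  if (min(fval) > 0.5 || max(fval) < 0.5) {
    rec$not_crossing <- TRUE
    rec$included <- FALSE
    rec$reason <- "fitted curve does not cross 0.5"
    return(rec)
  }
  i <- which.min(abs(fval - 0.5))   # which.min takes the first = shorter gap
  rec$threshold_ms <- grid[i]
  l <- stats::plogis(p$b * (log(grid[i]) - p$m))
  rec$slope_at_threshold <- (p$hi - p$lo) * p$b * l * (1 - l) / grid[i]
  rec
}

#' Exclude fits with extreme slopes at threshold
#'
#' Marks `included = FALSE` for fits whose absolute slope at threshold
#' exceeds `factor` times the median absolute slope across all supplied
#' fits (jointly over animals, stimuli and conditions).
#'
#' @param fits data.frame of stacked [fit_psychometric()] records.
#' @param factor exclusion multiple (default 10).
#' @return `fits` with updated `included`/`reason`.
#' @export
apply_slope_exclusion <- function(fits, factor = 10) {
  sl <- abs(fits$slope_at_threshold)
  if (sum(!is.na(sl)) < 2) {
    warning("fewer than two fits with slopes; no exclusion possible")
    return(fits)
  }
  cut <- factor * median(sl, na.rm = TRUE)
  drop <- !is.na(sl) & sl > cut
  fits$included[drop] <- FALSE
  fits$reason[drop] <- sprintf("slope at threshold > %g x median", factor)
  fits
}

#' Map a gap-detection threshold onto the normalized performance scale
#'
#' The seven gap lengths are assigned evenly spaced performance values:
#' 3 ms is 100% and each step down the series subtracts 100/7 percentage
#' points (85.71, 71.43, 57.14, 42.86, 28.57, 14.29). A continuous
#' threshold is either interpolated linearly on the log-gap axis between
#' neighbouring steps (default, matching thresholds "fitted on a
#' continuous scale"), or snapped to the nearest gap length on the log
#' axis before mapping.
#'
#' @param threshold_ms threshold(s) in ms, within \[3, 270\].
#' @param method `"interpolate"` (default) or `"snap"`.
#' @return normalized threshold in percent.
#' @export
normalize_threshold <- function(threshold_ms,
                                method = c("interpolate", "snap")) {
  method <- match.arg(method)
  if (any(threshold_ms < 3 | threshold_ms > 270, na.rm = TRUE)) {
    stop("threshold outside [3, 270] ms", call. = FALSE)
  }
  scale_pct <- 100 * (1 - (seq_along(GAP_LENGTHS_MS) - 1) / 7)
  if (method == "snap") {
    idx <- vapply(log(threshold_ms), function(lt) {
      which.min(abs(log(GAP_LENGTHS_MS) - lt))
    }, integer(1))
    scale_pct[idx]
  } else {
    approx(log(GAP_LENGTHS_MS), scale_pct, xout = log(threshold_ms))$y
  }
}

#' Score silence-detection sessions
#'
#' Removes trials with response times above 20 s, then drops sessions in
#' which any stimulus class (NBN, AM, silence) has fewer than 5 trials,
#' and returns per-class proportions correct and response-time summaries.
#'
#' @param trials silence-detection trial table (see
#'   [gen_silence_trials()]).
#' @param rt_cutoff_s response-time cutoff (default 20 s).
#' @param min_trials minimum trials per class per session (default 5).
#' @return list of class `silence_scores`: `scores` (data.frame
#'   `class_group`, `n`, `prop_correct`), `rt_summary` (per class x
#'   correctness median/mean RT), `sessions_retained`,
#'   `sessions_excluded`, `animal`, `condition`.
#' @export
score_silence_sessions <- function(trials, rt_cutoff_s = 20, min_trials = 5) {
  trials <- trials[!trials$correction & trials$rt_s <= rt_cutoff_s, ,
                   drop = FALSE]
  classes <- c("NBN", "AM", "silence")
  keep_session <- vapply(split(trials, trials$session), function(df) {
    counts <- table(factor(df$class_group, levels = classes))
    all(counts >= min_trials)
  }, logical(1))
  excluded <- names(keep_session)[!keep_session]
  kept <- trials[!(trials$session %in% excluded), , drop = FALSE]
  if (!nrow(kept)) {
    return(structure(list(scores = data.frame(class_group = classes,
                                              n = 0L, prop_correct = NA_real_),
                          rt_summary = NULL,
                          sessions_retained = character(0),
                          sessions_excluded = excluded,
                          animal = trials$animal[1] %||% NA,
                          condition = trials$condition[1] %||% NA),
                     class = "silence_scores"))
  }
  scores <- aggregate(correct ~ class_group, data = kept,
                      FUN = function(x) c(n = length(x), p = mean(x)))
  scores <- data.frame(class_group = scores$class_group,
                       n = scores$correct[, "n"],
                       prop_correct = scores$correct[, "p"])
  rt_summary <- aggregate(rt_s ~ class_group + correct, data = kept,
                          FUN = function(x) c(n = length(x),
                                              median = median(x),
                                              mean = mean(x)))
  structure(list(scores = scores, rt_summary = rt_summary,
                 sessions_retained = unique(kept$session),
                 sessions_excluded = excluded,
                 animal = kept$animal[1], condition = kept$condition[1]),
            class = "silence_scores")
}
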