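#' Continuous-sound detection change metric
#'
#' `M(cont) = Post / BL - 1`, where Post and BL are the proportions
#' correct on no-gap (continuous sound) trials, pooled across all tested
#' stimuli with sessions weighted equally. Positive values indicate
#' improved continuous-sound detection after exposure, consistent with a
#' continuous phantom sound.
#'
#' @param post_pc,bl_pc proportion correct on no-gap trials, post and
#'   baseline; `bl_pc` must be positive.
#' @return metric value (not clamped; negative = performance worsened).
#' @export
m_cont <- function(post_pc, bl_pc) {
  if (!is.finite(bl_pc) || bl_pc <= 0) {
    stop("M(cont) undefined: baseline proportion correct must be > 0",
         call. = FALSE)
  }
  post_pc / bl_pc - 1
}

#' Gap-threshold change metric
#'
#' `M(thresh) = 1 - Post / BL` on the normalized threshold scale
#' (percent; see [normalize_threshold()]). Positive values indicate an
#' elevated gap-detection threshold after exposure.
#'
#' @param post_norm,bl_norm normalized thresholds in percent, averaged
#'   across stimuli; `bl_norm` must be positive.
#' @return metric value.
#' @export
m_thresh <- function(post_norm, bl_norm) {
  if (!is.finite(bl_norm) || bl_norm <= 0) {
    stop("M(thresh) undefined: baseline normalized threshold must be > 0",
         call. = FALSE)
  }
  1 - post_norm / bl_norm
}

#' Silence-detection change metric
#'
#' `M(silence) = 1 - Post / BL`, where Post and BL are the proportions
#' correct on silence trials. Positive values indicate impaired silence
#' detection after exposure (e.g. a post/baseline ratio of 0.8 gives 0.2,
#' a 20% decrease relative to baseline).
#'
#' @param post_pc,bl_pc proportion correct on silence trials, post and
#'   baseline; `bl_pc` must be positive.
#' @return metric value.
#' @export
m_silence <- function(post_pc, bl_pc) {
  if (!is.finite(bl_pc) || bl_pc <= 0) {
    stop("M(silence) undefined: baseline proportion correct must be > 0",
         call. = FALSE)
  }
  1 - post_pc / bl_pc
}

#' Behavioural tinnitus index
#'
#' `TI = M(cont) + M(thresh) + M(silence)` (exact sum). All three
#' component metrics are signed: each is 0 when post-exposure equals
#' baseline performance and positive in the direction consistent with
#' tinnitus.
#'
#' @param m_cont,m_thresh,m_silence the three component metrics.
#' @param animal,condition_pair labels recorded in the report.
#' @param provenance optional list describing which fits/scores fed each
#'   metric.
#' @return one-row data.frame of class `tinnitus_index` with the three
#'   metrics and their sum `TI`; `provenance` attached as an attribute.
#' @export
tinnitus_index <- function(m_cont, m_thresh, m_silence, animal = NA_character_,
                           condition_pair = "BL vs Post",
                           provenance = NULL) {
  vals <- c(m_cont, m_thresh, m_silence)
  if (any(!is.finite(vals))) {
    stop("TI undefined: all three metrics must be finite", call. = FALSE)
  }
  out <- data.frame(animal = animal, condition_pair = condition_pair,
                    m_cont = m_cont, m_thresh = m_thresh,
                    m_silence = m_silence, TI = m_cont + m_thresh + m_silence,
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("tinnitus_index", "data.frame")
  out
}

#' Compute the tinnitus index from trial tables
#'
#' End-to-end convenience wrapper: filters and scores baseline and
#' post-exposure gap and silence trial tables, fits psychometric functions
#' per stimulus, averages normalized thresholds across stimuli (before the
#' ratio, by default), pools no-gap proportion correct across stimuli with
#' equal session weights, and assembles the TI report.
#'
#' @param gap_bl,gap_post gap-detection trial tables (baseline, post).
#' @param silence_bl,silence_post silence-detection trial tables.
#' @param normalize_method passed to [normalize_threshold()].
#' @param thresh_average `"before_ratio"` (default) averages normalized
#'   thresholds across stimuli and then takes the post/baseline ratio;
#'   `"after_ratio"` averages per-stimulus ratios instead.
#' @return [tinnitus_index()] report.
#' @export
compute_tinnitus_index <- function(gap_bl, gap_post, silence_bl, silence_post,
                                   normalize_method = "interpolate",
                                   thresh_average = c("before_ratio",
                                                      "after_ratio")) {
  thresh_average <- match.arg(thresh_average)
  prep <- function(trials) {
    t2 <- filter_gap_sessions(filter_gap_trials(trials))
    rates <- hit_and_fa_rates(t2)
    stimuli <- sort(unique(t2$stimulus))
    fits <- do.call(rbind, lapply(stimuli, function(s) {
      fit_psychometric(rates, animal = t2$animal[1], stimulus = s,
                       condition = t2$condition[1])
    }))
    list(rates = rates, fits = fits)
  }
  bl <- prep(gap_bl)
  post <- prep(gap_post)
  fits <- apply_slope_exclusion(rbind(bl$fits, post$fits))
  ok <- fits$included & !is.na(fits$threshold_ms)
  norm <- normalize_threshold(fits$threshold_ms[ok], method = normalize_method)
  cond <- fits$condition[ok]
  is_bl <- cond == fits$condition[1]
  if (thresh_average == "before_ratio") {
    mth <- m_thresh(mean(norm[!is_bl]), mean(norm[is_bl]))
  } else {
    stim <- fits$stimulus[ok]
    shared <- intersect(stim[is_bl], stim[!is_bl])
    ratios <- vapply(shared, function(s) {
      norm[!is_bl & stim == s] / norm[is_bl & stim == s]
    }, numeric(1))
    mth <- 1 - mean(ratios)
  }
  nogap_pc <- function(rates) mean(rates$fa$nogap_correct)
  mc <- m_cont(nogap_pc(post$rates), nogap_pc(bl$rates))
  sil_pc <- function(trials) {
    sc <- score_silence_sessions(trials)
    sc$scores$prop_correct[sc$scores$class_group == "silence"]
  }
  ms <- m_silence(sil_pc(silence_post), sil_pc(silence_bl))
  tinnitus_index(mc, mth, ms, animal = gap_bl$animal[1],
                 condition_pair = paste(gap_bl$condition[1], "vs",
                                        gap_post$condition[1]),
                 provenance = list(fits = fits,
                                   thresh_average = thresh_average))
}
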