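# Pairwise temporal-order analyses during cue presentation:
# cross-correlograms with baseline-normalized joint-probability change,
# and Z-scored spike-triggered averages with after-minus-before asymmetry.

# Per-bin lag counts of target spikes around trigger spikes, processed per
# cue window so pairs never straddle windows. Triggers whose bin would
# poke outside the window are excluded from that bin's normalizer
# (truncated windows, per-bin trigger counts).
pair_lag_counts <- function(trigger, target, windows, window_ms, bin_ms) {
  edges <- seq(-window_ms, window_ms, by = bin_ms)
  n_bins <- length(edges) - 1L
  counts <- integer(n_bins)
  n_contrib <- integer(n_bins)
  n_trig <- 0L
  n_tgt_in_win <- 0L
  for (w in seq_len(nrow(windows))) {
    w0 <- windows[w, 1L]; w1 <- windows[w, 2L]
    tg <- trigger[trigger >= w0 & trigger < w1]
    ta <- target[target >= w0 & target < w1]
    n_trig <- n_trig + length(tg)
    if (length(tg)) {
      lo <- edges[-length(edges)] / 1000
      hi <- edges[-1L] / 1000
      n_contrib <- n_contrib +
        (findInterval(w1 - hi, tg) - findInterval(w0 - lo - 1e-9, tg))
    }
    if (!length(tg) || !length(ta)) next
    lags_ms <- unlist(lapply(tg, function(t0) {
      i0 <- findInterval(t0 - window_ms / 1000 - 1e-9, ta) + 1L
      i1 <- findInterval(t0 + window_ms / 1000 - 1e-9, ta)
      if (i1 < i0) return(numeric(0))
      (ta[seq.int(i0, i1)] - t0) * 1000
    }))
    if (length(lags_ms)) {
      b <- findInterval(lags_ms, edges, rightmost.closed = FALSE)
      b <- b[b >= 1L & b <= n_bins]
      tb <- tabulate(b, n_bins)
      counts <- counts + tb
      n_tgt_in_win <- n_tgt_in_win + sum(tb)
    }
  }
  list(edges = edges, counts = counts, n_contrib = n_contrib,
       n_trigger = n_trig, n_target = n_tgt_in_win)
}

#' Cross-correlogram with joint-probability change from baseline
#'
#' Histogram of target-spike lags relative to each trigger spike within
#' the given cue windows. The joint probability per 1-ms bin is the count
#' divided by the number of contributing trigger spikes for that bin;
#' change is expressed relative to the mean joint probability over the
#' baseline period before the trigger (default 50 ms).
#'
#' @param trigger,target sorted spike-time vectors (seconds).
#' @param windows 2-column matrix of cue windows (start, end in seconds).
#' @param window_ms half-width of the correlogram (default 100).
#' @param bin_ms bin width (default 1).
#' @param baseline_ms baseline extent before the trigger (default 50).
#' @return a `crosscorr`: `lag_ms` (bin centres), `counts`, `joint_prob`,
#'   `delta` (joint probability minus baseline), `baseline`, `n_trigger`,
#'   `empty` flag.
#' @export
cross_correlogram <- function(trigger, target, windows, window_ms = 100,
                              bin_ms = 1, baseline_ms = 50) {
  pc <- pair_lag_counts(trigger, target, windows, window_ms, bin_ms)
  if (pc$n_trigger == 0L) {
    return(structure(list(lag_ms = numeric(0), counts = integer(0),
                          joint_prob = numeric(0), delta = numeric(0),
                          baseline = NA_real_, n_trigger = 0L, empty = TRUE),
                     class = "crosscorr"))
  }
  centre <- pc$edges[-length(pc$edges)] + bin_ms / 2
  jp <- ifelse(pc$n_contrib > 0L, pc$counts / pc$n_contrib, NA_real_)
  base_sel <- centre < 0 & centre >= -baseline_ms
  baseline <- mean(jp[base_sel], na.rm = TRUE)
  structure(list(lag_ms = centre, counts = pc$counts, joint_prob = jp,
                 delta = jp - baseline, baseline = baseline,
                 n_trigger = pc$n_trigger, empty = FALSE),
            class = "crosscorr")
}

#' Spike-triggered average of a directed unit pair
#'
#' Sums target spike counts in each 1-ms bin of a 200-ms window around
#' every trigger spike within the cue windows, then Z-scores the per-bin
#' average rate. Pairs whose target fires fewer than `min_target` spikes
#' across all trigger windows are excluded (explicit exclusion record,
#' not silent omission).
#'
#' @inheritParams cross_correlogram
#' @param min_target exclusion threshold on total target spikes in the
#'   trigger windows (default 20).
#' @param zscore `"within_sta"` normalizes by the mean/SD across the 200
#'   bins of the same STA; `"session_rate"` centres on the target's mean
#'   rate over the cue windows with a Poisson-scaled SD.
#' @return an `sta_result`: `lag_ms`, `z`, `rate_hz`, `n_trigger`,
#'   `n_target`, `included` flag.
#' @export
spike_triggered_average <- function(trigger, target, windows,
                                    window_ms = 100, bin_ms = 1,
                                    min_target = 20L,
                                    zscore = c("within_sta", "session_rate")) {
  zscore <- match.arg(zscore)
  pc <- pair_lag_counts(trigger, target, windows, window_ms, bin_ms)
  centre <- pc$edges[-length(pc$edges)] + bin_ms / 2
  if (pc$n_target < min_target || pc$n_trigger == 0L) {
    return(structure(list(lag_ms = centre, z = rep(NA_real_, length(centre)),
                          rate_hz = rep(NA_real_, length(centre)),
                          n_trigger = pc$n_trigger, n_target = pc$n_target,
                          included = FALSE, zscore = zscore),
                     class = "sta_result"))
  }
  rate <- ifelse(pc$n_contrib > 0L,
                 pc$counts / (pc$n_contrib * bin_ms / 1000), NA_real_)
  if (zscore == "within_sta") {
    z <- (rate - mean(rate, na.rm = TRUE)) / sd(rate, na.rm = TRUE)
  } else {
    tot_t <- sum(windows[, 2L] - windows[, 1L])
    n_tgt_all <- sum(vapply(seq_len(nrow(windows)), function(w)
      sum(target >= windows[w, 1L] & target < windows[w, 2L]), 1))
    mu <- n_tgt_all / tot_t
    se <- sqrt(mu / (pc$n_trigger * bin_ms / 1000))
    z <- (rate - mu) / se
  }
  structure(list(lag_ms = centre, z = z, rate_hz = rate,
                 n_trigger = pc$n_trigger, n_target = pc$n_target,
                 included = TRUE, zscore = zscore),
            class = "sta_result")
}

#' 5-ms moving average of an STA (display only)
#'
#' Smoothing used for visualization; statistics always run on the raw
#' 1-ms bins.
#'
#' @param sta an `sta_result`.
#' @param k window length in bins (default 5).
#' @return smoothed Z vector.
#' @export
sta_smooth <- function(sta, k = 5L) {
  as.numeric(stats::filter(sta$z, rep(1 / k, k), sides = 2))
}

#' After-minus-before STA asymmetry with bootstrap effect size
#'
#' Per included pair, the mean Z over post-trigger bins (0, +100] ms minus
#' the mean over pre-trigger bins [-100, 0) ms; the group effect is a
#' bias-corrected bootstrap of the mean asymmetry against zero. Positive
#' values mean the target tends to fire after the trigger.
#'
#' @param stas list of `sta_result` objects.
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @return list with `per_pair` asymmetries (included pairs), `effect`
#'   (an `effect_estimate`), `n_excluded`.
#' @export
sta_asymmetry <- function(stas, n_boot = 10000L, seed = 1L) {
  inc <- vapply(stas, function(s) isTRUE(s$included), TRUE)
  if (sum(inc) < 2L) stop("need at least 2 included pairs")
  asym <- vapply(stas[inc], function(s) {
    after <- s$lag_ms > 0
    mean(s$z[after], na.rm = TRUE) - mean(s$z[!after], na.rm = TRUE)
  }, 1)
  eff <- bootstrap_effect_size(asym, rep(0, length(asym)), n_boot = n_boot,
                               seed = seed, paired = TRUE)
  list(per_pair = asym, effect = eff, n_excluded = sum(!inc))
}
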