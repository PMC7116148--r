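# Trial-level behavior: decision-point filtering, reward-seeking bias,
# and bias-corrected bootstrap effect sizes.

# First transition into the area within the trial. A trial that starts
# with the animal already inside (e.g. an outcome window entered from the
# preceding cue's dwell) has no visit of its own: the filter exists to
# censor the approach to the dispenser, not occupancy carried over.
first_entry <- function(inside) {
  ent <- which(inside & !c(TRUE, inside[-length(inside)]))
  if (length(ent)) ent[1L] else NA_integer_
}

#' Decision point of a single trial
#'
#' The decision point is the latest time within the trial at which the
#' animal's speed is below the threshold (default 5 cm/s) and which
#' precedes the first entry into the outcome area. Activity after the
#' decision point is censored downstream, removing epochs where the animal
#' is at or approaching the dispenser.
#'
#' @param trial one row of the trial table (`onset`, `offset`, `win_end`).
#' @param pos position trace (`t`, `x`, `y`); speed is derived at the
#'   sampling rate.
#' @param poly outcome-area polygon (n x 2 matrix, cm).
#' @param speed_thr threshold (cm/s).
#' @return list with `time` (seconds or `NA`) and `status`: `"found"`,
#'   `"no_entry"` (animal never enters the area; keep the whole trial) or
#'   `"excluded"` (entry but no sub-threshold sample before it).
#' @export
decision_point <- function(trial, pos, poly, speed_thr = 5) {
  w0 <- trial$onset; w1 <- trial$win_end
  if (w0 < min(pos$t) - 1e-9 || w1 > max(pos$t) + 1e-9)
    stop(sprintf("trial %s window [%.2f, %.2f] not covered by position trace",
                 trial$trial_id, w0, w1))
  sel <- which(pos$t >= w0 & pos$t < w1)
  if (!length(sel)) return(list(time = NA_real_, status = "no_entry"))
  sp <- position_speed(pos)[sel]
  inside <- points_in_poly(pos$x[sel], pos$y[sel], poly)
  entry <- first_entry(inside)
  if (is.na(entry)) return(list(time = NA_real_, status = "no_entry"))
  slow <- which(sp[seq_len(entry - 1L)] < speed_thr)
  if (!length(slow)) return(list(time = NA_real_, status = "excluded"))
  list(time = pos$t[sel][max(slow)], status = "found")
}

#' Decision points for every trial of a session
#'
#' @param session a `session_data`.
#' @param speed_thr threshold (cm/s), default 5.
#' @return data.frame `trial_id`, `time`, `status` (see [decision_point()]).
#' @export
decision_points <- function(session, speed_thr = 5) {
  poly <- session$meta$arena$outcome_poly
  pos <- session$position
  sp <- position_speed(pos)
  inside_all <- points_in_poly(pos$x, pos$y, poly)
  tr <- session$trials
  n <- nrow(tr)
  time <- rep(NA_real_, n); status <- rep("no_entry", n)
  for (i in seq_len(n)) {
    i0 <- findInterval(tr$onset[i] - 1e-9, pos$t) + 1L
    i1 <- findInterval(tr$win_end[i] - 1e-9, pos$t)
    if (i1 < i0) next
    sel <- i0:i1
    entry <- first_entry(inside_all[sel])
    if (is.na(entry)) next
    slow <- which(sp[sel][seq_len(entry - 1L)] < speed_thr)
    if (length(slow)) {
      status[i] <- "found"; time[i] <- pos$t[sel][max(slow)]
    } else status[i] <- "excluded"
  }
  data.frame(trial_id = tr$trial_id, time = time, status = status)
}

#' Per-day reward-seeking bias (set 1 minus set 2)
#'
#' Quantifies reward seeking per trial, averages within set and day, and
#' returns the set-1 minus set-2 difference per day. Measures:
#' \describe{
#'   \item{`inference_window_20s`}{percentage of the post-cue window
#'     (auditory-cue offset to `win_end`) spent in the outcome area,
#'     inference-test trials.}
#'   \item{`conditioning_cue_window`}{percentage of the visual cue (prior
#'     to outcome delivery) spent in the outcome area, conditioning Yn
#'     trials.}
#'   \item{`visit_fraction`}{percentage of trials with at least one
#'     position sample in the outcome area.}
#' }
#'
#' @param session a `session_data`.
#' @param measure one of the measures above.
#' @return data.frame with `day`, `set1`, `set2`, `bias` (percentage
#'   points); days lacking trials of either set are omitted with a warning.
#' @export
reward_seeking_bias <- function(session,
                                measure = c("inference_window_20s",
                                            "conditioning_cue_window",
                                            "visit_fraction")) {
  measure <- match.arg(measure)
  poly <- session$meta$arena$outcome_poly
  pos <- session$position
  trials <- session$trials
  trials <- switch(measure,
    inference_window_20s = trials[trials$stage == "inference_test", ],
    conditioning_cue_window = trials[trials$stage == "conditioning" &
                                       substr(trials$cue, 1, 1) == "Y", ],
    visit_fraction = trials[trials$stage == "inference_test", ])
  if (!nrow(trials)) stop("no trials for measure ", measure)
  score <- vapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    w0 <- switch(measure,
                 inference_window_20s = tr$offset,
                 conditioning_cue_window = tr$onset,
                 visit_fraction = tr$onset)
    w1 <- switch(measure,
                 inference_window_20s = tr$win_end,
                 conditioning_cue_window = min(tr$offset, tr$outcome_time,
                                               na.rm = TRUE),
                 visit_fraction = tr$win_end)
    sel <- which(pos$t >= w0 & pos$t < w1)
    if (!length(sel)) return(NA_real_)
    inside <- points_in_poly(pos$x[sel], pos$y[sel], poly)
    if (measure == "visit_fraction") 100 * any(inside) else 100 * mean(inside)
  }, 1)
  out <- list()
  for (d in sort(unique(trials$day))) {
    m1 <- score[trials$day == d & trials$set == 1L]
    m2 <- score[trials$day == d & trials$set == 2L]
    if (!length(m1) || !length(m2)) {
      warning(sprintf("day %d omitted: no trials for one set", d))
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      day = d, set1 = mean(m1, na.rm = TRUE), set2 = mean(m2, na.rm = TRUE))
  }
  out <- do.call(rbind, out)
  out$bias <- out$set1 - out$set2
  out
}

#' Bias-corrected bootstrap effect size for a group difference
#'
#' Mean difference `mean(a) - mean(b)` with a bias-corrected-and-
#' accelerated (BCa) 95\% confidence interval from bootstrap resamples,
#' the estimation approach popularized by DABEST. The paired variant
#' resamples index-aligned pairs.
#'
#' @param a,b numeric vectors (equal length if `paired`).
#' @param n_boot number of resamples (>= 1000).
#' @param seed integer seed (resampling is seed-deterministic).
#' @param paired resample aligned pairs instead of independent groups.
#' @return an `effect_estimate`: `estimate`, `ci_low`, `ci_high`,
#'   `boot_dist`, `n_boot`, `seed`, `paired`, `degenerate`.
#' @export
bootstrap_effect_size <- function(a, b, n_boot = 10000L, seed = 1L,
                                  paired = FALSE) {
  if (!length(a) || !length(b)) stop("a and b must be non-empty")
  if (n_boot < 1000L) stop("n_boot must be >= 1000")
  if (paired && length(a) != length(b))
    stop("paired groups must have equal length")
  set.seed(as.integer(seed))
  if (paired) {
    d <- a - b
    bt <- boot::boot(d, function(x, i) mean(x[i]), R = n_boot)
  } else {
    dat <- data.frame(v = c(a, b),
                      g = rep(1:2, c(length(a), length(b))))
    bt <- boot::boot(dat, function(x, i) {
      xi <- x[i, ]
      mean(xi$v[xi$g == 1L]) - mean(xi$v[xi$g == 2L])
    }, R = n_boot, strata = dat$g)
  }
  est <- mean(a) - mean(b)
  dist <- as.numeric(bt$t)
  degenerate <- sd(dist) < .Machine$double.eps^0.5
  ci <- if (degenerate) c(est, est) else {
    bca <- tryCatch(boot::boot.ci(bt, type = "bca")$bca[4:5],
                    error = function(e) NULL)
    bca %||% as.numeric(quantile(dist, c(0.025, 0.975)))
  }
  structure(list(estimate = est, ci_low = ci[1L], ci_high = ci[2L],
                 boot_dist = dist, n_boot = n_boot, seed = seed,
                 paired = paired, degenerate = degenerate),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("mean difference %.4g, 95%% BCa CI [%.4g, %.4g] (%d resamples%s)\n",
              x$estimate, x$ci_low, x$ci_high, x$n_boot,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}
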