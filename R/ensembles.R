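# Cue-ensemble identification: 100-ms Z-scored binned rates filtered by
# the decision point, per-neuron cue GLMs, 2-SD ensemble assignment, and
# the time-resolved performance-modulation GLM.

count_in_bins <- function(st, lo, hi) {
  # st sorted spike times; bins [lo, hi). Rounding-safe epsilon below the
  # 0.1 ms spike resolution.
  findInterval(hi - 1e-9, st) - findInterval(lo - 1e-9, st)
}

#' Bin spike trains at 100 ms and Z-score per unit
#'
#' Counts spikes in fixed-width bins spanning each trial's cue window,
#' converts to Hz, masks bins after the trial's decision point (trials
#' whose decision point is undefined despite an outcome-area entry are
#' masked entirely), and Z-scores each unit across all included bins of
#' the session.
#'
#' @param session a `session_data`.
#' @param dps decision points from [decision_points()]; computed if `NULL`.
#' @param bin_s bin width in seconds (default 0.1).
#' @return a `binned_rates`: `z` (unit x bin matrix, Z-scored over included
#'   bins), `rate` (Hz), `bins` (per-bin trial/cue/day mapping with
#'   `included` mask), `zero_var` (units with no rate variance, flagged and
#'   to be excluded from downstream correlations), `bin_s`.
#' @export
bin_and_zscore <- function(session, dps = NULL, bin_s = 0.1) {
  if (is.null(dps)) dps <- decision_points(session,
                                           session$meta$decision_speed %||% 5)
  trials <- session$trials
  nb <- pmax(1L, floor((trials$offset - trials$onset) / bin_s + 1e-9))
  idx <- rep.int(seq_len(nrow(trials)), nb)
  off <- (sequence(nb) - 1L) * bin_s
  bins <- data.frame(trial_id = trials$trial_id[idx], day = trials$day[idx],
                     stage = trials$stage[idx], cue = trials$cue[idx],
                     set = trials$set[idx], correct = trials$correct[idx],
                     t0 = trials$onset[idx] + off,
                     t1 = trials$onset[idx] + off + bin_s)
  dp <- dps$time[match(bins$trial_id, dps$trial_id)]
  status <- dps$status[match(bins$trial_id, dps$trial_id)]
  bins$included <- status == "no_entry" |
    (status == "found" & bins$t1 <= dp + 1e-9)

  n_units <- session$meta$n_units
  rate <- matrix(0, n_units, nrow(bins))
  spl <- split(session$spikes$time_s, factor(session$spikes$unit_id,
                                             levels = seq_len(n_units)))
  for (u in seq_len(n_units))
    rate[u, ] <- count_in_bins(spl[[u]], bins$t0, bins$t1) / bin_s

  inc <- bins$included
  mu <- rowMeans(rate[, inc, drop = FALSE])
  sg <- apply(rate[, inc, drop = FALSE], 1L, sd)
  zero_var <- which(sg < .Machine$double.eps^0.5)
  sg[zero_var] <- 1
  z <- (rate - mu) / sg
  structure(list(z = z, rate = rate, bins = bins, zero_var = zero_var,
                 bin_s = bin_s, dps = dps),
            class = "binned_rates")
}

#' Per-neuron cue GLM
#'
#' For each unit, the decision-point-filtered Z-scored rate is averaged
#' within each trial and the per-trial averages are regressed on indicator
#' variables for the six task cues plus the standardized average running
#' speed of the trial (one indicator per cue, no intercept: each trial
#' presents exactly one cue). Ordinary least squares, since the response is
#' already a Z-scored rate.
#'
#' @param br a `binned_rates`.
#' @param session the `session_data` the rates came from (for speed).
#' @param days optional subset of days to fit on (default: all pooled).
#' @return a `cue_glm`: `weights` (unit x 6 cue matrix), `speed_weight`,
#'   `n_trials` per cue, `units_used`.
#' @export
fit_cue_glm <- function(br, session, days = NULL) {
  bins <- br$bins
  keep <- bins$included
  if (!is.null(days)) keep <- keep & bins$day %in% days
  tid <- unique(bins$trial_id[keep])
  # per-trial mean z per unit (rowsum over bins of each trial)
  f <- factor(bins$trial_id[keep], levels = tid)
  sums <- rowsum(t(br$z[, keep, drop = FALSE]), f)   # trials x units
  y <- t(sums / as.integer(table(f)))
  tr <- session$trials[match(tid, session$trials$trial_id), ]
  cues <- cue_levels()
  n_per <- table(factor(tr$cue, levels = cues))
  if (any(n_per < 2L))
    stop("rank-deficient design; cues with < 2 included trials: ",
         paste(cues[n_per < 2L], collapse = ", "))
  X <- sapply(cues, function(cu) as.numeric(tr$cue == cu))
  # mean running speed over the included portion of each trial
  pos <- session$position
  sp <- position_speed(pos)
  dpt <- br$dps$time[match(tid, br$dps$trial_id)]
  csp <- cumsum(sp)
  spd <- vapply(seq_len(nrow(tr)), function(i) {
    hi <- min(tr$offset[i], dpt[i], na.rm = TRUE)
    i0 <- findInterval(tr$onset[i] - 1e-9, pos$t) + 1L
    i1 <- findInterval(hi - 1e-9, pos$t)
    if (i1 < i0) 0 else (csp[i1] - csp[i0] + sp[i0]) / (i1 - i0 + 1L)
  }, 1)
  spd <- as.numeric(scale(spd))
  if (any(!is.finite(spd))) spd[] <- 0
  X <- cbind(X, speed = spd)
  beta <- solve(crossprod(X), crossprod(X, t(y)))
  structure(list(weights = t(beta[cues, , drop = FALSE]),
                 speed_weight = as.numeric(beta["speed", ]),
                 n_trials = as.integer(n_per),
                 units_used = seq_len(nrow(br$z)),
                 zero_var = br$zero_var),
            class = "cue_glm")
}

#' Assign neurons to cue-specific ensembles (2-SD rule)
#'
#' A unit joins the ensemble of a cue when its regression weight for that
#' cue is positive and exceeds the mean weight for that cue, computed
#' across all recorded units, by `k_sd` standard deviations.
#'
#' @param glm a `cue_glm`.
#' @param k_sd threshold in SD units (default 2).
#' @return an `ensemble_assignment`: `members` (cue-named list of unit
#'   ids), `thresholds`, `overlap` (units in more than one ensemble),
#'   `single` (units in exactly one ensemble).
#' @export
assign_ensembles <- function(glm, k_sd = 2) {
  w <- glm$weights
  if (nrow(w) < 10L)
    warning("fewer than 10 units; 2-SD threshold is unstable")
  cues <- colnames(w)
  thr <- vapply(cues, function(cu) mean(w[, cu]) + k_sd * sd(w[, cu]), 1)
  members <- lapply(cues, function(cu)
    which(w[, cu] > thr[cu] & w[, cu] > 0))
  names(members) <- cues
  counts <- table(unlist(members))
  overlap <- as.integer(names(counts)[counts > 1L])
  single <- as.integer(names(counts)[counts == 1L])
  structure(list(members = members, thresholds = thr, k_sd = k_sd,
                 overlap = overlap, single = single),
            class = "ensemble_assignment")
}

#' @export
print.ensemble_assignment <- function(x, ...) {
  sizes <- vapply(x$members, length, 1L)
  cat("<ensemble_assignment> ",
      paste(sprintf("%s:%d", names(sizes), sizes), collapse = " "),
      sprintf(" (%d units in >1 ensemble)\n", length(x$overlap)), sep = "")
  invisible(x)
}

#' Time-resolved performance-modulation GLM
#'
#' In each 100-ms bin of a peristimulus window around auditory-cue onset,
#' each unit's Z-scored rate across inference-test trials is regressed on
#' behavioral performance (1 = correct, 0 = incorrect inference) with the
#' trial's standardized average speed and cue set as covariates. Returns
#' the per-bin average performance weight across units with a unit-level
#' one-sample t-test.
#'
#' @param session a `session_data`.
#' @param window_s half-width of the peristimulus window (default 15 s).
#' @param bin_s bin width (default 0.1 s).
#' @param correct_labels optional replacement for the trials' correct
#'   flags (e.g. shuffled labels for a null calibration).
#' @param prep precomputed design from [performance_glm_design()]; saves
#'   re-binning when the same session is refit under many label shuffles.
#' @return a `perf_glm` data.frame: `t` (bin centre relative to onset),
#'   `mean_weight`, `t_stat`, `p` (two-sided); per-unit weights in
#'   `attr(, "weights")`.
#' @export
performance_modulation_glm <- function(session, window_s = 15, bin_s = 0.1,
                                       correct_labels = NULL, prep = NULL) {
  if (is.null(prep)) prep <- performance_glm_design(session, window_s, bin_s)
  tr <- prep$trials
  correct <- correct_labels %||% tr$correct
  if (length(unique(correct)) < 2L)
    stop("need both correct and incorrect trials")
  n_units <- prep$n_units; n_bins <- prep$n_bins
  Y <- prep$Y; edges <- prep$edges; bin_s <- prep$bin_s
  X <- cbind(1, correct = as.numeric(correct),
             speed = prep$speed_std,
             set = tr$set - 1.5)
  B <- solve(crossprod(X), crossprod(X, Y))   # 4 x (units*bins)
  wmat <- matrix(B["correct", ], nrow = n_units, ncol = n_bins, byrow = TRUE)
  mean_w <- colMeans(wmat)
  sd_w <- apply(wmat, 2L, sd)
  t_stat <- mean_w / (sd_w / sqrt(n_units))
  p <- 2 * pt(-abs(t_stat), df = n_units - 1L)
  out <- data.frame(t = edges[-length(edges)] + bin_s / 2,
                    mean_weight = mean_w, t_stat = t_stat, p = p)
  attr(out, "weights") <- wmat
  class(out) <- c("perf_glm", "data.frame")
  out
}

#' Peristimulus design for the performance-modulation GLM
#'
#' Bins and Z-scores every unit's rate in a peristimulus window around
#' each inference-test auditory-cue onset. Factored out so null
#' calibrations can refit [performance_modulation_glm()] under many label
#' shuffles without re-binning.
#'
#' @inheritParams performance_modulation_glm
#' @return list with the binned Z-rate matrix and trial covariates.
#' @export
performance_glm_design <- function(session, window_s = 15, bin_s = 0.1) {
  tr <- session$trials[session$trials$stage == "inference_test", ]
  if (!nrow(tr)) stop("no inference-test trials")
  n_units <- session$meta$n_units
  edges <- seq(-window_s, window_s, by = bin_s)
  n_bins <- length(edges) - 1L
  spl <- split(session$spikes$time_s, factor(session$spikes$unit_id,
                                             levels = seq_len(n_units)))
  n_tr <- nrow(tr)
  Y <- matrix(0, n_tr, n_units * n_bins)
  lo0 <- edges[-length(edges)]
  for (u in seq_len(n_units)) {
    st <- spl[[u]]
    cols <- (u - 1L) * n_bins + seq_len(n_bins)
    for (i in seq_len(n_tr)) {
      lo <- tr$onset[i] + lo0
      Y[i, cols] <- count_in_bins(st, lo, lo + bin_s) / bin_s
    }
  }
  mu <- colMeans(Y); sg <- apply(Y, 2L, sd)
  ok <- sg > .Machine$double.eps^0.5
  Y[, ok] <- sweep(sweep(Y[, ok, drop = FALSE], 2L, mu[ok]), 2L, sg[ok], "/")
  Y[, !ok] <- 0
  pos <- session$position; sp <- position_speed(pos)
  spd <- vapply(seq_len(n_tr), function(i) {
    sel <- pos$t >= tr$onset[i] - window_s & pos$t < tr$onset[i] + window_s
    mean(sp[sel])
  }, 1)
  spd <- as.numeric(scale(spd))
  if (any(!is.finite(spd))) spd[] <- 0
  list(Y = Y, trials = tr, speed_std = spd, edges = edges,
       n_units = n_units, n_bins = n_bins, bin_s = bin_s)
}
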