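# Sharp-wave ripple detection and coactivation analyses: normalized
# triplet/doublet joint-firing probabilities with early-vs-late contrasts,
# shuffle controls, SWR co-firing correlations, first-spike-order tests.

#' Detect sharp-wave ripples from an LFP trace
#'
#' Subtracts the reference channel (common-mode removal), band-pass
#' filters (default 135-250 Hz), computes an RMS power envelope, and marks
#' events where the envelope exceeds the background mean by
#' `threshold_sd` standard deviations during immobility (speed below
#' `immobility_speed`). Background statistics are computed over immobility
#' samples only. Event edges extend to `edge_sd` crossings; events shorter
#' than `min_dur_s` are dropped and events separated by less than
#' `merge_gap_s` are merged.
#'
#' @param lfp an `lfp_trace` (see [generate_lfp()]).
#' @param session the `session_data` supplying the speed trace and epochs.
#' @param band ripple band (Hz).
#' @param threshold_sd detection threshold in SD units (default 7).
#' @param edge_sd edge-extension threshold (default 2).
#' @param min_dur_s minimum event duration (default 0.02 s).
#' @param merge_gap_s merge gap (default 0.01 s).
#' @param rms_win_s RMS envelope window (default 0.01 s).
#' @param immobility_speed immobility threshold, cm/s (default 1.5).
#' @return an `swr_set` data.frame: `event_id`, `day`, `start`, `end`,
#'   `peak_sd`, `context`, `source = "detected"`.
#' @export
detect_swrs <- function(lfp, session, band = c(135, 250), threshold_sd = 7,
                        edge_sd = 2, min_dur_s = 0.02, merge_gap_s = 0.01,
                        rms_win_s = 0.01, immobility_speed = 1.5) {
  if (lfp$rate < 2 * band[2L])
    stop(sprintf("LFP rate %g Hz below Nyquist for band edge %g Hz",
                 lfp$rate, band[2L]))
  pos <- session$position
  sp <- position_speed(pos)
  out <- list(); ev_id <- 0L
  any_immobile <- FALSE
  for (seg in lfp$segments) {
    n <- length(seg$lfp)
    tt <- seg$t0 + seq_len(n) / seg$rate
    proc <- seg$lfp - seg$ref
    bp <- bandpass_filter(proc, seg$rate, band)
    k <- max(3L, round(rms_win_s * seg$rate))
    env <- sqrt(as.numeric(stats::filter(bp^2, rep(1 / k, k), sides = 2)))
    env[is.na(env)] <- 0
    idx <- pmin(pmax(findInterval(tt, pos$t), 1L), length(sp))
    immobile <- sp[idx] < immobility_speed
    if (!any(immobile)) next
    any_immobile <- TRUE
    mu <- mean(env[immobile]); sg <- sd(env[immobile])
    if (!is.finite(sg) || sg < .Machine$double.eps) next  # flat signal
    z <- (env - mu) / sg
    core <- z > threshold_sd & immobile
    if (!any(core)) next
    above_edge <- z > edge_sd & immobile
    r <- rle(above_edge)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    ints <- NULL
    for (j in which(r$values)) {
      s0 <- starts[j]; s1 <- ends[j]
      if (!any(core[s0:s1])) next
      ints <- rbind(ints, c(tt[s0], tt[s1]))
    }
    if (is.null(ints)) next
    ints <- merge_intervals(ints, gap = merge_gap_s)
    keep <- (ints[, 2L] - ints[, 1L]) >= min_dur_s
    ints <- ints[keep, , drop = FALSE]
    for (j in seq_len(nrow(ints))) {
      ev_id <- ev_id + 1L
      sel <- tt >= ints[j, 1L] & tt <= ints[j, 2L]
      out[[ev_id]] <- data.frame(
        event_id = ev_id, day = seg$day, start = ints[j, 1L],
        end = ints[j, 2L], peak_sd = max(z[sel]),
        context = seg$context, source = "detected")
    }
  }
  if (!any_immobile) warning("no immobility samples; empty SWR set")
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(event_id = integer(), day = integer(), start = numeric(),
               end = numeric(), peak_sd = numeric(), context = character(),
               source = character())
  class(res) <- c("swr_set", "data.frame")
  res
}

#' Ground-truth SWR events as an `swr_set`
#'
#' @param truth a `ground_truth`.
#' @return an `swr_set` with `source = "ground_truth"`.
#' @export
truth_swr_set <- function(truth) {
  ev <- truth$swr_events
  if (nrow(ev)) {
    ev$peak_sd <- NA_real_
    ev$source <- "ground_truth"
  } else {
    ev$peak_sd <- numeric(0); ev$source <- character(0)
  }
  class(ev) <- c("swr_set", "data.frame")
  ev
}

#' Event-by-unit spike-count participation matrix
#'
#' @param swrs an `swr_set`.
#' @param session a `session_data` (spike source).
#' @return integer matrix (events x units) of spike counts within event
#'   bounds; binarize with `>= 1` for participation.
#' @export
participation_matrix <- function(swrs, session) {
  n_units <- session$meta$n_units
  m <- matrix(0L, nrow(swrs), n_units)
  spl <- split(session$spikes$time_s, factor(session$spikes$unit_id,
                                             levels = seq_len(n_units)))
  for (u in seq_len(n_units))
    m[, u] <- count_in_bins(spl[[u]], swrs$start, swrs$end)
  rownames(m) <- as.character(swrs$event_id)
  m
}

day_durations <- function(session, days) {
  tr <- session$trials; ep <- session$epochs
  vapply(days, function(d) {
    lo <- min(c(ep$start[ep$day == d], tr$onset[tr$day == d]))
    hi <- max(c(ep$end[ep$day == d], tr$win_end[tr$day == d]))
    hi - lo
  }, 1)
}

epoch_mean_rates <- function(session, days) {
  tr <- session$trials; ep <- session$epochs
  lo <- min(c(ep$start[ep$day %in% days], tr$onset[tr$day %in% days]))
  hi <- max(c(ep$end[ep$day %in% days], tr$win_end[tr$day %in% days]))
  dur <- sum(day_durations(session, days))
  n_units <- session$meta$n_units
  cnt <- tabulate(session$spikes$unit_id[session$spikes$time_s >= lo &
                                           session$spikes$time_s < hi],
                  n_units)
  cnt / dur
}

#' Normalized joint-firing (coactivation) probability per tuple
#'
#' For each unit tuple, computes within each epoch (early/late day split)
#' the fraction of SWRs in which every member fired, normalized by the
#' tuple's average firing rate:
#' p-hat = (n / N) / f-bar, where n is the number of SWRs with all members
#' active, N the total number of SWRs in the epoch, and f-bar the mean of
#' the members' session mean rates over the epoch's days. Reports
#' p-hat_diff = p-hat_late - p-hat_early. Tuples never coactive in any SWR
#' are excluded, as are tuples with a zero-rate member (logged).
#'
#' @param session a `session_data`.
#' @param swrs an `swr_set`.
#' @param part participation matrix from [participation_matrix()] (rows
#'   aligned with `swrs`).
#' @param tuples list; each element a list with `units` (integer ids),
#'   `set` (1 or 2) and optional `label`.
#' @param day_split list with integer `early` and `late` day vectors
#'   (default days 1-4 vs 5-8).
#' @param context behavioral context to analyze (default `"awake_rest"`).
#' @param exclude_units optional unit ids (e.g. the Yn ensemble): SWRs in
#'   which any of these fired are not counted in n (the "in the absence of
#'   Yn" doublet variant); N is unchanged.
#' @return a `coactivation_result` data.frame with per-tuple columns
#'   `label`, `set`, `n_early`, `N_early`, `f_early`, `p_early`, the late
#'   counterparts, and `p_diff`.
#' @export
triplet_coactivation <- function(session, swrs, part, tuples,
                                 day_split = list(early = 1:4, late = 5:8),
                                 context = "awake_rest",
                                 exclude_units = NULL) {
  ev_ok <- swrs$context == context
  rates <- list(
    early = epoch_mean_rates(session, day_split$early),
    late = epoch_mean_rates(session, day_split$late))
  rows <- list(); skipped <- 0L
  for (tp in tuples) {
    u <- tp$units
    vals <- list()
    zero_rate <- FALSE
    for (ep in c("early", "late")) {
      sel <- ev_ok & swrs$day %in% day_split[[ep]]
      N <- sum(sel)
      co <- if (N)
        rowSums(part[sel, u, drop = FALSE] >= 1L) == length(u) else logical(0)
      if (!is.null(exclude_units)) {
        y_off <- rowSums(part[sel, exclude_units, drop = FALSE] >= 1L) == 0L
        co <- co & y_off
      }
      n <- sum(co)
      f <- mean(rates[[ep]][u])
      if (f <= 0) zero_rate <- TRUE
      vals[[ep]] <- c(n = n, N = N, f = f,
                      p = if (N > 0 && f > 0) (n / N) / f else NA_real_)
    }
    if (zero_rate) { skipped <- skipped + 1L; next }
    if (vals$early[["n"]] + vals$late[["n"]] == 0L) next  # never coactive
    rows[[length(rows) + 1L]] <- data.frame(
      label = tp$label %||% paste(u, collapse = "-"),
      set = tp$set,
      n_early = as.integer(vals$early[["n"]]),
      N_early = as.integer(vals$early[["N"]]),
      f_early = vals$early[["f"]], p_early = vals$early[["p"]],
      n_late = as.integer(vals$late[["n"]]),
      N_late = as.integer(vals$late[["N"]]),
      f_late = vals$late[["f"]], p_late = vals$late[["p"]])
  }
  if (skipped) message(skipped, " tuple(s) skipped: zero epoch rate")
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(), set = integer(), n_early = integer(),
               N_early = integer(), f_early = numeric(), p_early = numeric(),
               n_late = integer(), N_late = integer(), f_late = numeric(),
               p_late = numeric())
  res$p_diff <- res$p_late - res$p_early
  class(res) <- c("coactivation_result", "data.frame")
  res
}

#' Bootstrap effect size and set-by-day ANOVA for coactivation
#'
#' Per set, the mean early-to-late change in normalized coactivation
#' probability with a bias-corrected bootstrap CI; across all tuples, a
#' two-way ANOVA of p-hat on set x day (early/late) with Tukey's HSD post
#' hoc on the interaction cells.
#'
#' @param results a `coactivation_result`.
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @return list: `effects` (per-set `effect_estimate` of p_diff vs 0),
#'   `anova` (data.frame of the set:day row: F, df, p), `tukey`
#'   (TukeyHSD interaction table), `fit` (the aov object).
#' @export
coactivation_bootstrap <- function(results, n_boot = 10000L, seed = 1L) {
  long <- rbind(
    data.frame(set = factor(results$set, levels = 1:2),
               day = factor("early", c("early", "late")),
               p = results$p_early),
    data.frame(set = factor(results$set, levels = 1:2),
               day = factor("late", c("early", "late")),
               p = results$p_late))
  cells <- table(long$set, long$day)
  if (any(cells < 2L)) {
    bad <- which(cells < 2L, arr.ind = TRUE)[1L, ]
    stop(sprintf("design cell set %s / %s day has < 2 tuples",
                 rownames(cells)[bad[1L]], colnames(cells)[bad[2L]]))
  }
  fit <- aov(p ~ set * day, data = long)
  tab <- anova(fit)
  inter <- tab["set:day", ]
  effects <- lapply(sort(unique(results$set)), function(s) {
    d <- results$p_diff[results$set == s]
    bootstrap_effect_size(d, rep(0, length(d)), n_boot = n_boot,
                          seed = derive_seed(seed, s), paired = TRUE)
  })
  names(effects) <- paste0("set", sort(unique(results$set)))
  list(effects = effects,
       anova = data.frame(F = inter[["F value"]], df1 = inter[["Df"]],
                          df2 = tab["Residuals", "Df"],
                          p = inter[["Pr(>F)"]]),
       tukey = TukeyHSD(fit, "set:day")$`set:day`,
       fit = fit)
}

#' Shuffle control: permute which SWRs carry X spikes
#'
#' Holds Z participation fixed and, within each epoch, randomly reassigns
#' the set of SWRs containing X spikes (participation count preserved
#' exactly, hence the X cell's firing rate too), recomputing the
#' early-to-late change in the joint-participation fraction each time.
#' One-sided add-one p-value for the observed change against the null.
#'
#' @param part participation matrix.
#' @param swrs the aligned `swr_set`.
#' @param x_unit,z_unit unit ids.
#' @param day_split early/late day lists.
#' @param context behavioral context (default `"awake_rest"`).
#' @param n_perm permutations (default 10000).
#' @param seed integer seed.
#' @return list `observed`, `p`, `null`, `degenerate` (X fires in all or
#'   no SWRs of an epoch: the null is a point mass).
#' @export
swr_shuffle_control <- function(part, swrs, x_unit, z_unit,
                                day_split = list(early = 1:4, late = 5:8),
                                context = "awake_rest",
                                n_perm = 10000L, seed = 1L) {
  sel_ep <- lapply(day_split, function(d)
    which(swrs$context == context & swrs$day %in% d))
  x_p <- lapply(sel_ep, function(i) part[i, x_unit] >= 1L)
  z_p <- lapply(sel_ep, function(i) part[i, z_unit] >= 1L)
  if (sum(unlist(x_p)) == 0L || sum(unlist(z_p)) == 0L)
    stop("x and z units must participate in at least one SWR each")
  frac <- function(xe, ze) if (length(xe)) mean(xe & ze) else NA_real_
  observed <- frac(x_p$late, z_p$late) - frac(x_p$early, z_p$early)
  degenerate <- any(vapply(x_p, function(v) all(v) || !any(v), TRUE))
  set.seed(as.integer(seed))
  null <- vapply(seq_len(n_perm), function(i) {
    xs <- lapply(x_p, function(v) {
      w <- rep(FALSE, length(v))
      w[sample.int(length(v), sum(v))] <- TRUE
      w
    })
    frac(xs$late, z_p$late) - frac(xs$early, z_p$early)
  }, 1)
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  list(observed = observed, p = p, null = null, degenerate = degenerate)
}

#' Pairwise SWR co-firing correlations
#'
#' Pearson correlation between the per-event spike counts of every unit
#' pair across SWRs. Pairs with zero count variance are NA.
#'
#' @param part participation (count) matrix, events x units.
#' @param min_events warn below this many events (default 10).
#' @return symmetric units x units correlation matrix, NA diagonal.
#' @export
swr_cofire_correlation <- function(part, min_events = 10L) {
  if (nrow(part) < min_events)
    warning("fewer than ", min_events, " SWRs; correlations unstable")
  v <- apply(part, 2L, var)
  r <- suppressWarnings(cor(part))
  r[v == 0, ] <- NA_real_
  r[, v == 0] <- NA_real_
  diag(r) <- NA_real_
  r
}

#' First-spike-order test within SWRs (Zn - Xn)
#'
#' For each (X, Z) pair and each SWR in which both fire, takes the first
#' spike of each unit in the ripple and forms the interval
#' delta-t = t_first(Z) - t_first(X); ties are dropped (count logged). A
#' pair is "Z-first" when its median delta-t is negative. The fraction of
#' Z-first pairs is tested against 0.5 with a two-sided binomial test.
#'
#' @param swrs an `swr_set`.
#' @param session a `session_data`.
#' @param pairs data.frame with columns `x` and `z` (unit ids).
#' @param context behavioral context (default `"awake_rest"`).
#' @return list: `per_pair` (median delta-t and event count per pair),
#'   `fraction_z_first`, `binom_p`, `n_pairs`, `n_ties_dropped`.
#' @export
first_spike_order <- function(swrs, session, pairs,
                              context = "awake_rest") {
  swrs <- swrs[swrs$context == context, , drop = FALSE]
  spl <- split(session$spikes$time_s,
               factor(session$spikes$unit_id,
                      levels = seq_len(session$meta$n_units)))
  first_in <- function(st, lo, hi) {
    i <- findInterval(lo - 1e-9, st) + 1L
    if (i <= length(st) && st[i] < hi) st[i] else NA_real_
  }
  ties <- 0L
  per_pair <- lapply(seq_len(nrow(pairs)), function(k) {
    xs <- spl[[pairs$x[k]]]; zs <- spl[[pairs$z[k]]]
    dts <- vapply(seq_len(nrow(swrs)), function(e) {
      fx <- first_in(xs, swrs$start[e], swrs$end[e])
      fz <- first_in(zs, swrs$start[e], swrs$end[e])
      if (is.na(fx) || is.na(fz)) NA_real_ else fz - fx
    }, 1)
    dts <- dts[!is.na(dts)]
    nt <- sum(dts == 0)
    ties <<- ties + nt
    dts <- dts[dts != 0]
    data.frame(x = pairs$x[k], z = pairs$z[k],
               median_dt = if (length(dts)) median(dts) else NA_real_,
               n_events = length(dts))
  })
  per_pair <- do.call(rbind, per_pair)
  ok <- !is.na(per_pair$median_dt)
  frac <- mean(per_pair$median_dt[ok] < 0)
  bt <- if (any(ok))
    binom.test(sum(per_pair$median_dt[ok] < 0), sum(ok), p = 0.5) else NULL
  list(per_pair = per_pair, fraction_z_first = frac,
       binom_p = if (is.null(bt)) NA_real_ else bt$p.value,
       n_pairs = sum(ok), n_ties_dropped = ties)
}
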