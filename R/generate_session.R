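# Synthetic session generation: trial schedule, position path, spike
# trains (inhomogeneous-Poisson thinning), planted SWR coactivation.

# --- path builder ---------------------------------------------------------
# Knot-based trajectory: piecewise-linear (t, x, y) knots, later sampled at
# pos_rate. Still segments jitter within ~0.05 cm so immobility speed stays
# far below 1.5 cm/s; roam segments run at 8-13 cm/s so only planted dips
# fall below the 5 cm/s decision threshold.

path_new <- function(t0, xy) {
  env <- new.env(parent = emptyenv())
  env$t <- list(t0); env$x <- list(xy[1L]); env$y <- list(xy[2L])
  env$cur_t <- t0; env$cur <- xy
  env
}

path_knot <- function(p, t, xy) {
  if (t <= p$cur_t + 1e-9) return(invisible(p))
  p$t[[length(p$t) + 1L]] <- t
  p$x[[length(p$x) + 1L]] <- xy[1L]
  p$y[[length(p$y) + 1L]] <- xy[2L]
  p$cur_t <- t; p$cur <- xy
  invisible(p)
}

path_still <- function(p, t_end, jitter = 0.05) {
  while (p$cur_t + 0.4 < t_end) {
    xy <- p$cur + runif(2L, -jitter, jitter)
    path_knot(p, p$cur_t + 0.4, xy)
  }
  path_knot(p, t_end, p$cur)
}

path_goto <- function(p, xy, speed) {
  d <- sqrt(sum((xy - p$cur)^2))
  path_knot(p, p$cur_t + max(d / speed, 0.04), xy)
}

path_roam <- function(p, t_end, box) {
  while (p$cur_t < t_end - 1e-6) {
    tgt <- c(runif(1L, box[1L], box[2L]), runif(1L, box[3L], box[4L]))
    v <- runif(1L, 8, 13)
    d <- sqrt(sum((tgt - p$cur)^2))
    if (d < 1) next
    dur <- d / v
    if (p$cur_t + dur > t_end) {
      frac <- (t_end - p$cur_t) / dur
      path_knot(p, t_end, p$cur + frac * (tgt - p$cur))
    } else {
      path_knot(p, p$cur_t + dur, tgt)
    }
  }
}

# Approach the outcome area for a visiting trial: reach a staging point
# outside the area, hold still through the planted decision dip at t_dip,
# then run to the dispenser at 6.5 cm/s (above the 5 cm/s threshold), so
# the latest sub-threshold time before area entry is t_dip.
path_visit <- function(p, t_dip, staging, dispenser) {
  avail <- t_dip - 0.25 - p$cur_t
  d <- sqrt(sum((staging - p$cur)^2))
  sp <- min(max(d / max(avail, 0.3), 6), 20)
  path_goto(p, staging, sp)
  path_still(p, t_dip, jitter = 0.04)
  path_goto(p, dispenser, 6.5)
}

# --- main generator -------------------------------------------------------

#' Generate a synthetic multi-day session with planted ground truth
#'
#' Builds a full session on one clock: each day opens with an immobile
#' rest block (containing planted SWR events), followed by conditioning
#' trials (visual cue Yn then outcome Zn) and inference-test trials
#' (auditory cue Xn alone, with a reward-seeking window after offset).
#' Spike trains are inhomogeneous Poisson, thinned from
#' rate = baseline x (1 + gain during the preferred cue) + speed coupling,
#' with optional performance/prospective modulation on correct inference
#' trials, planted millisecond echo lags during auditory cues, and planted
#' SWR co-firing.
#'
#' @param config a [synth_config()].
#' @return list with elements `session` (class `session_data`: `spikes`,
#'   `trials`, `position`, `epochs`, `meta`) and `truth` (class
#'   `ground_truth`: tuning map, decision points, SWR events and
#'   participants, planted lags).
#' @export
generate_session <- function(config) {
  validate_synth_config(config)
  set.seed(as.integer(config$seed))

  n_units <- as.integer(config$n_units)
  baseline <- config$baseline_rate
  if (is.null(baseline)) {
    baseline <- rlnorm(n_units, meanlog = log(1.5), sdlog = 0.5)
  } else {
    baseline <- rep_len(baseline, n_units)
  }

  cues <- cue_levels()
  tuning <- rep(NA_character_, n_units)
  if (!is.null(config$tuning_map)) {
    for (cu in names(config$tuning_map))
      tuning[config$tuning_map[[cu]]] <- cu
  } else {
    n_per_cue <- round(config$tuned_fraction * n_units)
    if (n_per_cue * 6L > n_units)
      stop_field("tuned_fraction", "6 non-overlapping ensembles exceed n_units")
    if (n_per_cue > 0L) {
      pool <- sample.int(n_units, n_per_cue * 6L)
      for (i in seq_along(cues))
        tuning[pool[seq.int((i - 1L) * n_per_cue + 1L, i * n_per_cue)]] <- cues[i]
    }
  }

  poly <- config$arena$outcome_poly
  dispenser <- colMeans(poly)
  roam_box <- c(2, min(poly[, 1L]) - 8, 2, config$arena$h - 2)
  staging <- c(min(poly[, 1L]) - 9, dispenser[2L])
  rest_xy <- c(6, 6)

  # --- schedule trials and build path -------------------------------------
  trials <- list(); epochs <- list(); dps <- list()
  p <- path_new(0, rest_xy)
  t_cur <- 0; trial_id <- 0L
  cue_on <- list()  # per cue: list of c(start, end, correct01)

  for (day in seq_len(config$n_days)) {
    if (config$rest_s > 0) {
      path_still(p, t_cur + config$rest_s)
      epochs[[length(epochs) + 1L]] <-
        data.frame(day = day, start = t_cur, end = t_cur + config$rest_s,
                   context = "awake_rest")
      t_cur <- t_cur + config$rest_s
    }
    path_roam(p, t_cur + 2, roam_box); t_cur <- t_cur + 2

    balanced_sets <- function(n) {
      s <- rep(1:2, length.out = n)
      sample(s)
    }

    # conditioning: Yn cue then Zn outcome window
    n_cond <- as.integer(config$trials_per_day[["conditioning"]])
    sets <- balanced_sets(n_cond)
    for (k in seq_len(n_cond)) {
      s <- sets[k]
      y_on <- t_cur; y_off <- y_on + config$cue_s[["visual"]]
      z_on <- y_off; z_off <- z_on + config$cue_s[["outcome"]]
      visit <- runif(1L) < config$visit_prob[s]
      dp_t <- NA_real_
      if (visit) {
        u <- runif(1L, 3.0, 3.8)
        dp_t <- y_on + u
        path_roam(p, dp_t - 3, roam_box)
        path_visit(p, dp_t, staging + runif(2L, -2, 2),
                   dispenser + runif(2L, -1, 1))
        dwell_end <- min(p$cur_t + config$occupancy[s] * config$cue_s[["visual"]],
                         y_off - 0.1)
        path_still(p, dwell_end, jitter = 0.04)
        path_goto(p, c(roam_box[2L] - 2, runif(1L, 10, 40)), 10)
      }
      t_cur <- z_off + config$iti_s
      path_roam(p, t_cur, roam_box)
      trial_id <- trial_id + 1L
      trials[[length(trials) + 1L]] <- data.frame(
        trial_id = trial_id, day = day, block = 1L, stage = "conditioning",
        cue = paste0("Y", s), set = s, onset = y_on, offset = y_off,
        win_end = y_off, outcome_time = z_on, correct = NA)
      dps[[length(dps) + 1L]] <- data.frame(trial_id = trial_id, t = dp_t)
      cue_on[[paste0("Y", s)]] <- c(cue_on[[paste0("Y", s)]], list(c(y_on, y_off, NA)))
      trial_id <- trial_id + 1L
      trials[[length(trials) + 1L]] <- data.frame(
        trial_id = trial_id, day = day, block = 1L, stage = "conditioning",
        cue = paste0("Z", s), set = s, onset = z_on, offset = z_off,
        win_end = z_off, outcome_time = z_on, correct = NA)
      dps[[length(dps) + 1L]] <- data.frame(trial_id = trial_id, t = NA_real_)
      cue_on[[paste0("Z", s)]] <- c(cue_on[[paste0("Z", s)]], list(c(z_on, z_off, NA)))
    }

    # inference test: Xn alone + reward-seeking window
    n_inf <- as.integer(config$trials_per_day[["inference_test"]])
    sets <- balanced_sets(n_inf)
    for (k in seq_len(n_inf)) {
      s <- sets[k]
      x_on <- t_cur; x_off <- x_on + config$cue_s[["auditory"]]
      w_end <- x_off + config$post_window_s
      correct <- runif(1L) < config$p_correct
      visit <- runif(1L) < config$visit_prob[s]
      dp_t <- NA_real_
      if (visit) {
        u <- runif(1L, 3, 6)
        dp_t <- x_on + u
        path_roam(p, dp_t - 3, roam_box)
        path_visit(p, dp_t, staging + runif(2L, -2, 2),
                   dispenser + runif(2L, -1, 1))
        dwell_end <- max(p$cur_t, x_off) + config$occupancy[s] * config$post_window_s
        path_still(p, dwell_end, jitter = 0.04)
        path_goto(p, c(roam_box[2L] - 2, runif(1L, 10, 40)), 10)
      }
      t_cur <- w_end + config$iti_s
      path_roam(p, t_cur, roam_box)
      trial_id <- trial_id + 1L
      trials[[length(trials) + 1L]] <- data.frame(
        trial_id = trial_id, day = day, block = 2L, stage = "inference_test",
        cue = paste0("X", s), set = s, onset = x_on, offset = x_off,
        win_end = w_end, outcome_time = NA_real_, correct = correct)
      dps[[length(dps) + 1L]] <- data.frame(trial_id = trial_id, t = dp_t)
      cue_on[[paste0("X", s)]] <-
        c(cue_on[[paste0("X", s)]], list(c(x_on, x_off, as.numeric(correct))))
    }
  }
  t_end <- t_cur + 2
  path_roam(p, t_end, roam_box)

  trials <- do.call(rbind, trials)
  dps <- do.call(rbind, dps)
  epochs <- if (length(epochs)) do.call(rbind, epochs) else
    data.frame(day = integer(), start = numeric(), end = numeric(),
               context = character())

  # --- sample position at pos_rate ----------------------------------------
  kt <- unlist(p$t); kx <- unlist(p$x); ky <- unlist(p$y)
  ts <- seq(0, t_end, by = 1 / config$pos_rate)
  position <- data.frame(
    t = ts,
    x = approx(kt, kx, xout = ts, rule = 2)$y,
    y = approx(kt, ky, xout = ts, rule = 2)$y)
  speed <- position_speed(position)

  # --- spikes: inhomogeneous-Poisson thinning per unit ---------------------
  cue_win <- lapply(cue_on, function(l) do.call(rbind, l))
  xy_assoc <- c(X1 = "Y1", X2 = "Y2")
  max_extra <- max(config$perf_gain, config$prospective_gain)
  smax <- max(speed)
  spk <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    rmax <- baseline[u] * (1 + config$tuning_gain) * (1 + max_extra) +
      config$speed_coupling * smax + 1e-9
    n_cand <- rpois(1L, rmax * t_end)
    cand <- sort(runif(n_cand, 0, t_end))
    lam <- rep(baseline[u], n_cand)
    pref <- tuning[u]
    if (!is.na(pref) && !is.null(cue_win[[pref]])) {
      w <- cue_win[[pref]]
      lam[in_any_interval(cand, w[, 1:2, drop = FALSE])] <-
        baseline[u] * (1 + config$tuning_gain)
    }
    extra_w <- NULL
    if (!is.na(pref)) {
      if (config$perf_gain > 0 && pref %in% c("X1", "X2")) {
        w <- cue_win[[pref]]
        if (!is.null(w)) extra_w <- w[w[, 3L] == 1, , drop = FALSE]
      }
      if (config$prospective_gain > 0 && pref %in% c("Y1", "Y2")) {
        xn <- names(xy_assoc)[match(pref, xy_assoc)]
        w <- cue_win[[xn]]
        if (!is.null(w)) extra_w <- w[w[, 3L] == 1, , drop = FALSE]
      }
    }
    if (!is.null(extra_w) && nrow(extra_w)) {
      g <- if (config$perf_gain > 0 && pref %in% c("X1", "X2"))
        config$perf_gain else config$prospective_gain
      sel <- in_any_interval(cand, extra_w[, 1:2, drop = FALSE])
      lam[sel] <- lam[sel] * (1 + g)
    }
    idx <- pmin(floor(cand * config$pos_rate) + 1L, length(speed))
    lam <- lam + config$speed_coupling * speed[idx]
    keep <- runif(n_cand) < lam / rmax
    spk[[u]] <- cand[keep]
  }

  # planted millisecond echoes during auditory cues
  x_win <- rbind(cue_win[["X1"]], cue_win[["X2"]])
  if (!is.null(config$planted_lag_ms) && nrow(config$planted_lag_ms) &&
      !is.null(x_win)) {
    for (i in seq_len(nrow(config$planted_lag_ms))) {
      row <- config$planted_lag_ms[i, ]
      w <- x_win
      if (isTRUE(row$correct_only))
        w <- w[w[, 3L] == 1, , drop = FALSE]
      trig <- spk[[row$trigger]]
      trig <- trig[in_any_interval(trig, w[, 1:2, drop = FALSE])]
      sel <- trig[runif(length(trig)) < row$prob]
      spk[[row$target]] <- c(spk[[row$target]], sel + row$lag_ms / 1000)
    }
  }

  # SWR events inside rest blocks, with planted coactivation
  swr_events <- list(); swr_parts <- list()
  ev_id <- 0L
  for (r in seq_len(nrow(epochs))) {
    ep <- epochs[r, ]
    n_ev <- rpois(1L, config$swr_rate * (ep$end - ep$start - 2))
    if (n_ev == 0L) next
    starts <- sort(runif(n_ev, ep$start + 1, ep$end - 1 - config$swr_duration))
    keep <- c(TRUE, diff(starts) > config$swr_duration + 0.05)
    starts <- starts[keep]
    for (s0 in starts) {
      ev_id <- ev_id + 1L
      e0 <- s0 + config$swr_duration
      parts <- integer(0)
      for (cs in config$coactivation_sets) {
        if (!(ep$day %in% cs$days)) next
        if (runif(1L) >= cs$prob) next
        lag <- cs$lag_ms %||% rep(0, length(cs$units))
        pad <- max(lag) / 1000
        base_t <- runif(1L, s0, max(e0 - pad - 1e-4, s0 + 1e-4))
        for (j in seq_along(cs$units)) {
          uu <- cs$units[j]
          if (is.null(cs$lag_ms)) {
            tj <- runif(1L, s0, e0)
          } else {
            tj <- min(base_t + lag[j] / 1000, e0 - 1e-5)
          }
          spk[[uu]] <- c(spk[[uu]], tj)
        }
        parts <- union(parts, cs$units)
      }
      swr_events[[ev_id]] <- data.frame(
        event_id = ev_id, day = ep$day, start = s0, end = e0,
        context = ep$context)
      swr_parts[[ev_id]] <- sort(parts)
    }
  }
  swr_events <- if (length(swr_events)) do.call(rbind, swr_events) else
    data.frame(event_id = integer(), day = integer(), start = numeric(),
               end = numeric(), context = character())

  spk <- lapply(spk, function(s) unique(sort(round(s, 4))))  # 0.1 ms grid
  spikes <- data.frame(
    unit_id = rep.int(seq_len(n_units), vapply(spk, length, 1L)),
    time_s = unlist(spk))

  session <- structure(list(
    spikes = spikes,
    trials = trials,
    position = position,
    epochs = epochs,
    meta = list(n_units = n_units, n_days = as.integer(config$n_days),
                subject = "synthetic", pos_rate = config$pos_rate,
                t_end = t_end, arena = config$arena,
                baseline_rate = baseline,
                decision_speed = config$decision_speed,
                immobility_speed = config$immobility_speed)
  ), class = "session_data")

  truth <- structure(list(
    tuning = tuning,
    decision_points = dps,
    swr_events = swr_events,
    swr_participants = swr_parts,
    lags = config$planted_lag_ms,
    config = config
  ), class = "ground_truth")

  list(session = session, truth = truth)
}

#' Instantaneous speed from a position trace
#'
#' Finite-difference speed in cm/s at the position sampling rate; the first
#' sample repeats the second so the trace has no leading NA.
#'
#' @param position data.frame with columns `t`, `x`, `y`.
#' @return numeric vector of speeds, same length as the trace.
#' @export
position_speed <- function(position) {
  dt <- diff(position$t)
  v <- sqrt(diff(position$x)^2 + diff(position$y)^2) / dt
  c(v[1L], v)
}

#' @export
print.session_data <- function(x, ...) {
  cat(sprintf("<session_data> %d units, %d days, %d trials, %.0f s, %d spikes\n",
              x$meta$n_units, x$meta$n_days, nrow(x$trials), x$meta$t_end,
              nrow(x$spikes)))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d tuned units, %d SWR events, %d planted decision points\n",
              sum(!is.na(x$tuning)), nrow(x$swr_events),
              sum(!is.na(x$decision_points$t))))
  invisible(x)
}
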