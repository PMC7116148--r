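# Session directory layout: plain-text readers/writers (CSV + JSON), an
# end-to-end pipeline driver, and exporters. All times in seconds on one
# session clock; intervals half-open [start, end).

fmt_num_df <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  df
}

#' Write a session (and optional ground truth) to a directory
#'
#' Layout: `spikes.csv` (unit_id, time_s), `trials.csv`, `position.csv`
#' (t, x, y), `epochs.csv`, `meta.json`, and `ground_truth.json` when
#' truth is given. Doubles are written with 17 significant digits so the
#' loader round-trips losslessly.
#'
#' @param session a `session_data`.
#' @param path directory (created if missing).
#' @param truth optional `ground_truth`.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, truth = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write.csv(fmt_num_df(session$spikes), file.path(path, "spikes.csv"),
            row.names = FALSE)
  write.csv(fmt_num_df(session$trials), file.path(path, "trials.csv"),
            row.names = FALSE)
  write.csv(fmt_num_df(session$position), file.path(path, "position.csv"),
            row.names = FALSE)
  write.csv(fmt_num_df(session$epochs), file.path(path, "epochs.csv"),
            row.names = FALSE)
  meta <- session$meta
  meta$arena$outcome_poly <- unclass(meta$arena$outcome_poly)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    gt <- list(tuning = truth$tuning,
               decision_points = truth$decision_points,
               swr_events = truth$swr_events,
               swr_participants = truth$swr_participants,
               lags = truth$lags)
    jsonlite::write_json(gt, file.path(path, "ground_truth.json"),
                         digits = NA, na = "null")
  }
  invisible(path)
}

#' Load a session directory
#'
#' Validates the layout: required files present, schema columns, strictly
#' increasing position timestamps, non-decreasing per-unit spike times,
#' `offset > onset` per trial (error names the row), and trial windows
#' covered by the position trace.
#'
#' @param path session directory written by [write_session()].
#' @return a `session_data` (with `truth` attached as attribute
#'   `"truth"` if `ground_truth.json` is present).
#' @export
load_session <- function(path) {
  need <- c("spikes.csv", "trials.csv", "position.csv", "epochs.csv",
            "meta.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("missing session files: ", paste(missing, collapse = ", "))
  spikes <- read.csv(file.path(path, "spikes.csv"))
  if (!all(c("unit_id", "time_s") %in% names(spikes)))
    stop("spikes.csv: expected columns unit_id, time_s")
  trials <- read.csv(file.path(path, "trials.csv"))
  tneed <- c("trial_id", "day", "stage", "cue", "set", "onset", "offset",
             "win_end")
  if (!all(tneed %in% names(trials)))
    stop("trials.csv: expected columns ", paste(tneed, collapse = ", "))
  bad <- which(trials$offset <= trials$onset)
  if (length(bad))
    stop("trials.csv: offset <= onset at row(s) ",
         paste(head(bad, 5L), collapse = ", "))
  position <- read.csv(file.path(path, "position.csv"))
  if (!all(c("t", "x", "y") %in% names(position)))
    stop("position.csv: expected columns t, x, y")
  if (is.unsorted(position$t, strictly = TRUE))
    stop("position.csv: timestamps must be strictly increasing")
  for (u in unique(spikes$unit_id)) {
    if (is.unsorted(spikes$time_s[spikes$unit_id == u]))
      stop("spikes.csv: non-monotone spike times for unit ", u)
  }
  epochs <- read.csv(file.path(path, "epochs.csv"))
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  meta$arena$outcome_poly <- as.matrix(meta$arena$outcome_poly)
  if (nrow(trials) && (min(trials$onset) < min(position$t) - 1e-6 ||
                       max(trials$win_end) > max(position$t) + 1e-6))
    stop("trial windows extend beyond position-trace coverage")
  session <- structure(list(spikes = spikes, trials = trials,
                            position = position, epochs = epochs,
                            meta = meta),
                       class = "session_data")
  gt_path <- file.path(path, "ground_truth.json")
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    attr(session, "truth") <- gt
  }
  session
}

#' Export ensemble assignments as JSON
#' @param ens an `ensemble_assignment`.
#' @param path output file.
#' @export
export_ensembles_json <- function(ens, path) {
  jsonlite::write_json(list(members = ens$members,
                            thresholds = as.list(ens$thresholds),
                            k_sd = ens$k_sd, overlap = ens$overlap),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export SWR events as a BED-like tab-separated interval file
#' @param swrs an `swr_set`.
#' @param path output file.
#' @export
export_swr_tsv <- function(swrs, path) {
  df <- data.frame(start = sprintf("%.6f", swrs$start),
                   end = sprintf("%.6f", swrs$end),
                   peak_sd = sprintf("%.3f", swrs$peak_sd),
                   context = swrs$context, day = swrs$day)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic-demo pipeline
#'
#' Generates a session, then runs the behavior, ensemble, RSA,
#' spike-timing and SWR stages, writing JSON results, interval files and a
#' plain-text report to `out_dir`. Every threshold and seed used is
#' logged in the report. Stages can be disabled; later stages reuse the
#' artifacts of earlier ones.
#'
#' @param config a [synth_config()] (its `seed` drives every stage).
#' @param out_dir output directory.
#' @param stages subset of
#'   `c("behavior", "ensembles", "rsa", "timing", "swr")`.
#' @param n_perm permutations for RSA inference (default 1000).
#' @param n_boot bootstrap resamples (default 2000).
#' @param write_session_files also write the session CSV layout.
#' @return the report list, invisibly; `report.txt` and `results.json`
#'   land in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("behavior", "ensembles", "rsa",
                                    "timing", "swr"),
                         n_perm = 1000L, n_boot = 2000L,
                         write_session_files = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed,
                 params = list(decision_speed = config$decision_speed,
                               immobility_speed = config$immobility_speed,
                               swr_band = config$swr_band,
                               threshold_sd = 7, edge_sd = 2,
                               k_sd = 2, bin_s = 0.1,
                               n_perm = n_perm, n_boot = n_boot))
  gen <- generate_session(config)
  session <- gen$session; truth <- gen$truth
  report$session <- list(n_units = session$meta$n_units,
                         n_days = session$meta$n_days,
                         n_trials = nrow(session$trials),
                         n_spikes = nrow(session$spikes))
  if (write_session_files)
    write_session(session, file.path(out_dir, "session"), truth)

  dps <- decision_points(session, config$decision_speed)
  br <- NULL; ens <- NULL

  if ("behavior" %in% stages) {
    bias <- reward_seeking_bias(session, "inference_window_20s")
    eff <- bootstrap_effect_size(bias$set1, bias$set2, n_boot = n_boot,
                                 seed = derive_seed(config$seed, 11L),
                                 paired = TRUE)
    report$behavior <- list(
      bias_per_day = bias,
      n_decision_found = sum(dps$status == "found"),
      n_excluded = sum(dps$status == "excluded"),
      effect = list(estimate = eff$estimate, ci = c(eff$ci_low, eff$ci_high)))
  }
  if (any(c("ensembles", "rsa", "timing", "swr") %in% stages)) {
    br <- bin_and_zscore(session, dps)
    glm <- fit_cue_glm(br, session)
    ens <- assign_ensembles(glm)
    export_ensembles_json(ens, file.path(out_dir, "ensembles.json"))
    report$ensembles <- lapply(ens$members, length)
  }
  if ("rsa" %in% stages) {
    days <- sort(unique(session$trials$day))
    rsms <- lapply(days, function(d) {
      te <- population_vectors(br, c("X1", "X2"), split = "correct", days = d)
      tr <- population_vectors(br, c("Y1", "Y2"), days = d)
      cross_rsm(te, tr)
    })
    wmb <- vapply(rsms, within_minus_between, 1)
    gi <- group_inference(wmb)
    pt <- permutation_null(rsms, n_perm = n_perm,
                           seed = derive_seed(config$seed, 21L))
    report$rsa <- list(within_minus_between = mean(wmb),
                       wilcoxon_p = gi$p, permutation_p = pt$p)
  }
  if ("timing" %in% stages) {
    x_win <- as.matrix(session$trials[session$trials$cue %in% c("X1", "X2"),
                                      c("onset", "offset")])
    prs <- list()
    for (s in 1:2) {
      xs <- ens$members[[paste0("X", s)]]
      ys <- ens$members[[paste0("Y", s)]]
      for (a in head(xs, 4L)) for (b in head(ys, 4L))
        prs[[length(prs) + 1L]] <- c(a, b)
    }
    stas <- lapply(prs, function(pr) {
      spk <- session$spikes
      spike_triggered_average(spk$time_s[spk$unit_id == pr[1L]],
                              spk$time_s[spk$unit_id == pr[2L]], x_win)
    })
    inc <- vapply(stas, function(s) isTRUE(s$included), TRUE)
    report$timing <- if (sum(inc) >= 2L) {
      asym <- sta_asymmetry(stas, n_boot = n_boot,
                            seed = derive_seed(config$seed, 31L))
      list(n_pairs = sum(inc),
           asymmetry = asym$effect$estimate,
           ci = c(asym$effect$ci_low, asym$effect$ci_high))
    } else list(n_pairs = sum(inc))
  }
  if ("swr" %in% stages) {
    lfp <- generate_lfp(config, truth, session$epochs)
    swrs <- detect_swrs(lfp, session, band = config$swr_band,
                        immobility_speed = config$immobility_speed)
    export_swr_tsv(swrs, file.path(out_dir, "swr_events.tsv"))
    part <- participation_matrix(swrs, session)
    write.csv(part, file.path(out_dir, "participation.csv"))
    report$swr <- list(n_events = nrow(swrs))
    tuples <- list()
    for (s in 1:2) {
      xs <- intersect(ens$members[[paste0("X", s)]], ens$single)
      ys <- intersect(ens$members[[paste0("Y", s)]], ens$single)
      zs <- intersect(ens$members[[paste0("Z", s)]], ens$single)
      if (length(xs) && length(ys) && length(zs))
        for (x in head(xs, 3L)) for (y in head(ys, 3L)) for (z in head(zs, 3L))
          tuples[[length(tuples) + 1L]] <-
            list(units = c(x, y, z), set = s)
    }
    if (length(tuples) && nrow(swrs)) {
      half <- ceiling(session$meta$n_days / 2)
      split_days <- list(early = seq_len(half),
                         late = seq.int(half + 1L, session$meta$n_days))
      co <- triplet_coactivation(session, swrs, part, tuples, split_days)
      report$swr$n_tuples <- nrow(co)
      if (nrow(co) >= 4L && length(unique(co$set)) == 2L) {
        cb <- tryCatch(coactivation_bootstrap(co, n_boot = n_boot,
                                              seed = derive_seed(config$seed, 41L)),
                       error = function(e) NULL)
        if (!is.null(cb))
          report$swr$interaction <- list(F = cb$anova$F, p = cb$anova$p)
      }
    }
  }
  jsonlite::write_json(report, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  writeLines(format_report(report), file.path(out_dir, "report.txt"))
  invisible(report)
}

format_report <- function(report) {
  num <- function(x) sprintf("%.6g", x)
  out <- c("synthetic-session pipeline report",
           sprintf("seed: %s", report$seed),
           sprintf("params: decision %g cm/s, immobility %g cm/s, band %g-%g Hz, 7 SD / 2 SD edges, k_sd 2, bin 0.1 s",
                   report$params$decision_speed, report$params$immobility_speed,
                   report$params$swr_band[1L], report$params$swr_band[2L]),
           sprintf("session: %d units, %d days, %d trials, %d spikes",
                   report$session$n_units, report$session$n_days,
                   report$session$n_trials, report$session$n_spikes))
  if (!is.null(report$behavior))
    out <- c(out, sprintf("behavior: bias %s pp, CI [%s, %s], %d decision points",
                          num(report$behavior$effect$estimate),
                          num(report$behavior$effect$ci[1L]),
                          num(report$behavior$effect$ci[2L]),
                          report$behavior$n_decision_found))
  if (!is.null(report$ensembles))
    out <- c(out, paste0("ensembles: ",
                         paste(sprintf("%s=%d", names(report$ensembles),
                                       unlist(report$ensembles)),
                               collapse = " ")))
  if (!is.null(report$rsa))
    out <- c(out, sprintf("rsa: within-between %s, wilcoxon p %s, perm p %s",
                          num(report$rsa$within_minus_between),
                          num(report$rsa$wilcoxon_p),
                          num(report$rsa$permutation_p)))
  if (!is.null(report$timing) && !is.null(report$timing$asymmetry))
    out <- c(out, sprintf("timing: %d pairs, asymmetry %s, CI [%s, %s]",
                          report$timing$n_pairs, num(report$timing$asymmetry),
                          num(report$timing$ci[1L]), num(report$timing$ci[2L])))
  if (!is.null(report$swr))
    out <- c(out, sprintf("swr: %d events%s", report$swr$n_events,
                          if (!is.null(report$swr$interaction))
                            sprintf(", interaction F %s p %s",
                                    num(report$swr$interaction$F),
                                    num(report$swr$interaction$p)) else ""))
  out
}
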