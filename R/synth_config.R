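#' Configuration for the synthetic-session generator
#'
#' Defines the study conditions emulated by [generate_session()]: a
#' sensory-preconditioning task in an open field with six cues (auditory
#' X1/X2 presented alone on inference-test trials, visual Y1/Y2 followed by
#' outcome Z1/Z2 on conditioning trials), cue-tuned Poisson-like units,
#' speed-coupled rate modulation, immobile rest blocks containing
#' sharp-wave ripples (SWRs) in which configurable unit subsets co-fire,
#' and a position trace with an outcome area around the dispenser.
#'
#' Defaults follow the recorded task where stated (up to 8 test days,
#' 26 inference trials/day, 10-s auditory and 8-s visual cues, 10-s outcome
#' availability, 25-Hz position tracking, 135-250 Hz ripple band) and
#' field-typical conventions elsewhere (lognormal baseline rates centred in
#' 0.5-5 Hz, 0.3 SWR/s during immobility, 80-ms events).
#'
#' @param n_units number of recorded units.
#' @param n_days number of recording days.
#' @param trials_per_day named counts per stage:
#'   `observational`, `conditioning`, `inference_test`. Conditioning counts
#'   are visual-cue trials; each also yields an outcome (Zn) window.
#' @param cue_s named durations (seconds): `auditory`, `visual`, `outcome`.
#' @param post_window_s reward-seeking window after auditory-cue offset.
#' @param iti_s inter-trial interval (seconds).
#' @param rest_s duration of the immobile rest block opening each day.
#' @param baseline_rate per-unit baseline rates (Hz). A scalar is recycled;
#'   `NULL` draws lognormal rates (meanlog `log(1.5)`, sdlog `0.5`).
#' @param tuned_fraction fraction of units tuned to each cue.
#' @param tuning_map optional explicit assignment: named list, cue id to
#'   integer unit ids (disjoint across cues). Overrides the random
#'   `tuned_fraction` draw, so planted pairs can be placed on known units.
#' @param tuning_gain multiplicative rate increase during the preferred cue.
#' @param speed_coupling rate gain in Hz per cm/s of running speed.
#' @param perf_gain extra multiplicative gain for auditory-tuned units
#'   during their cue on correct inference trials (performance modulation).
#' @param prospective_gain extra gain for Yn-tuned units during the
#'   associated Xn cue on correct inference trials (prospective code).
#' @param p_correct probability an inference-test trial is "correct".
#' @param visit_prob per-set probability of visiting the outcome area on a
#'   trial, `c(set1, set2)`.
#' @param occupancy per-set planted fraction of the measure window spent in
#'   the outcome area, `c(set1, set2)`.
#' @param swr_rate SWR events per second of rest-block immobility.
#' @param swr_duration SWR duration (seconds).
#' @param swr_band ripple band (Hz), low < high.
#' @param swr_freq burst oscillation frequency (Hz), inside `swr_band`.
#' @param swr_snr burst amplitude in multiples of background ripple-band
#'   RMS used by [generate_lfp()].
#' @param coactivation_sets list of planted SWR coactivations; each element
#'   a list with `units` (integer ids), `prob` (per-event participation
#'   probability), `days` (integer day schedule) and optional `lag_ms`
#'   (per-unit spike-time offsets inside the event, controls first-spike
#'   order).
#' @param planted_lag_ms data.frame with columns `trigger`, `target`,
#'   `lag_ms`, `prob`: during auditory cues, each trigger spike elicits a
#'   target spike at the given lag with the given probability. An optional
#'   logical `correct_only` column restricts the echo to correct
#'   inference-test trials.
#' @param arena list: width `w`, height `h` (cm) and `outcome_poly`, an
#'   n x 2 vertex matrix for the outcome area.
#' @param pos_rate position sampling rate (Hz).
#' @param lfp_rate LFP sampling rate (Hz).
#' @param immobility_speed immobility threshold (cm/s) for SWR context.
#' @param decision_speed decision-point speed threshold (cm/s).
#' @param seed integer seed; same seed + config gives identical output.
#'
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_units = 100L,
                         n_days = 8L,
                         trials_per_day = c(observational = 0L,
                                            conditioning = 24L,
                                            inference_test = 26L),
                         cue_s = c(auditory = 10, visual = 8, outcome = 10),
                         post_window_s = 20,
                         iti_s = 5,
                         rest_s = 180,
                         baseline_rate = NULL,
                         tuned_fraction = 0.08,
                         tuning_map = NULL,
                         tuning_gain = 5,
                         speed_coupling = 0.02,
                         perf_gain = 0,
                         prospective_gain = 0,
                         p_correct = 0.7,
                         visit_prob = c(1, 1),
                         occupancy = c(0.30, 0.10),
                         swr_rate = 0.3,
                         swr_duration = 0.08,
                         swr_band = c(135, 250),
                         swr_freq = 190,
                         swr_snr = 10,
                         coactivation_sets = list(),
                         planted_lag_ms = NULL,
                         arena = list(w = 50, h = 50,
                                      outcome_poly = rbind(c(40, 40), c(50, 40),
                                                           c(50, 50), c(40, 50))),
                         pos_rate = 25,
                         lfp_rate = 1000,
                         immobility_speed = 1.5,
                         decision_speed = 5,
                         seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  check_scalar_pos(cfg$n_units, "n_units")
  check_scalar_pos(cfg$n_days, "n_days")
  for (st in c("observational", "conditioning", "inference_test")) {
    n <- cfg$trials_per_day[[st]]
    if (is.null(n) || !is.numeric(n) || n < 0)
      stop_field("trials_per_day", sprintf("missing or negative count for '%s'", st))
  }
  for (cu in c("auditory", "visual", "outcome"))
    check_scalar_pos(cfg$cue_s[[cu]], sprintf("cue_s[%s]", cu))
  check_scalar_pos(cfg$post_window_s, "post_window_s")
  check_scalar_pos(cfg$iti_s, "iti_s")
  check_scalar_pos(cfg$rest_s, "rest_s", allow_zero = TRUE)
  if (!is.null(cfg$baseline_rate) && any(cfg$baseline_rate < 0))
    stop_field("baseline_rate", "must be >= 0")
  if (cfg$tuned_fraction < 0 || cfg$tuned_fraction > 1)
    stop_field("tuned_fraction", "must lie in [0, 1]")
  if (!is.null(cfg$tuning_map)) {
    if (!all(names(cfg$tuning_map) %in% cue_levels()))
      stop_field("tuning_map", "names must be cue ids (X1..Z2)")
    ids <- unlist(cfg$tuning_map)
    if (any(ids < 1L | ids > cfg$n_units))
      stop_field("tuning_map", "unit ids outside 1..n_units")
    if (anyDuplicated(ids))
      stop_field("tuning_map", "unit ids must be disjoint across cues")
  }
  check_scalar_pos(cfg$tuning_gain, "tuning_gain", allow_zero = TRUE)
  check_scalar_pos(cfg$speed_coupling, "speed_coupling", allow_zero = TRUE)
  check_scalar_pos(cfg$perf_gain, "perf_gain", allow_zero = TRUE)
  check_scalar_pos(cfg$prospective_gain, "prospective_gain", allow_zero = TRUE)
  if (cfg$p_correct < 0 || cfg$p_correct > 1)
    stop_field("p_correct", "must lie in [0, 1]")
  if (length(cfg$visit_prob) != 2L || any(cfg$visit_prob < 0 | cfg$visit_prob > 1))
    stop_field("visit_prob", "must be two probabilities")
  if (length(cfg$occupancy) != 2L || any(cfg$occupancy < 0 | cfg$occupancy > 0.6))
    stop_field("occupancy", "must be two fractions in [0, 0.6]")
  check_scalar_pos(cfg$swr_rate, "swr_rate", allow_zero = TRUE)
  check_scalar_pos(cfg$swr_duration, "swr_duration")
  if (length(cfg$swr_band) != 2L || cfg$swr_band[1L] >= cfg$swr_band[2L])
    stop_field("swr_band", "low must be < high")
  if (cfg$swr_freq <= cfg$swr_band[1L] || cfg$swr_freq >= cfg$swr_band[2L])
    stop_field("swr_freq", "must lie inside swr_band")
  check_scalar_pos(cfg$swr_snr, "swr_snr")
  for (i in seq_along(cfg$coactivation_sets)) {
    cs <- cfg$coactivation_sets[[i]]
    if (is.null(cs$units) || is.null(cs$prob) || is.null(cs$days))
      stop_field("coactivation_sets", sprintf("element %d needs units, prob, days", i))
    if (any(cs$units < 1L | cs$units > cfg$n_units))
      stop_field("coactivation_sets", sprintf("element %d has unit ids outside 1..n_units", i))
    if (cs$prob < 0 || cs$prob > 1)
      stop_field("coactivation_sets", sprintf("element %d prob outside [0,1]", i))
    if (!is.null(cs$lag_ms) && length(cs$lag_ms) != length(cs$units))
      stop_field("coactivation_sets", sprintf("element %d lag_ms length mismatch", i))
  }
  if (!is.null(cfg$planted_lag_ms)) {
    need <- c("trigger", "target", "lag_ms", "prob")
    if (!all(need %in% names(cfg$planted_lag_ms)))
      stop_field("planted_lag_ms", "needs columns trigger, target, lag_ms, prob")
  }
  if (is.null(cfg$arena$outcome_poly) || ncol(cfg$arena$outcome_poly) != 2L)
    stop_field("arena", "outcome_poly must be an n x 2 matrix")
  check_scalar_pos(cfg$pos_rate, "pos_rate")
  check_scalar_pos(cfg$lfp_rate, "lfp_rate")
  if (cfg$lfp_rate < 2 * cfg$swr_band[2L])
    stop_field("lfp_rate", "must be at least twice the ripple-band upper edge")
  check_scalar_pos(cfg$immobility_speed, "immobility_speed")
  check_scalar_pos(cfg$decision_speed, "decision_speed")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L)
    stop_field("seed", "must be a single integer")
  invisible(cfg)
}
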