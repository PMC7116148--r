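# Shared configuration for the analysis drivers. Sourced by the numbered
# scripts; everything downstream reads the session written by 01_simulate.R.

library(hippens)

RESULTS_DIR <- "results"
SESSION_DIR <- file.path(RESULTS_DIR, "session")
GLOBAL_SEED <- 20260926L

# Demo-scale study conditions: 8 recording days, each opening with a rest
# block, then reconditioning (visual cue -> outcome) and inference-test
# (auditory cue alone) trials. Ensembles of 4 units per cue at gain 5
# (explicit tuning map so planted pairs land on known units); set-1 SWR
# coactivation ramps from 2% to 10% participation across the early/late
# day split, with Z-before-X first-spike ordering; set-2 stays flat. A
# prospective code (Y-ensemble firing during the associated X cue on
# correct trials) drives the RSA pattern, and set-1 X units elicit echo
# spikes in set-1 Y units at +8 ms during the auditory cues for the
# spike-timing analyses.
demo_config <- function() {
  tmap <- list(X1 = 1:4, X2 = 5:8, Y1 = 9:12, Y2 = 13:16,
               Z1 = 17:20, Z2 = 21:24)
  lags <- expand.grid(trigger = 1:4, target = 9:12)
  lags$lag_ms <- 8; lags$prob <- 0.12; lags$correct_only <- TRUE
  co <- list(); tp <- list(); u <- 31L
  for (s in 1:2) for (k in 1:6) {
    units <- u:(u + 2L); u <- u + 3L
    lag <- if (s == 1L) c(5, 2, 0) else NULL
    co[[length(co) + 1L]] <- list(units = units, prob = 0.02, days = 1:4,
                                  lag_ms = lag)
    co[[length(co) + 1L]] <- list(units = units,
                                  prob = if (s == 1L) 0.10 else 0.02,
                                  days = 5:8, lag_ms = lag)
    tp[[length(tp) + 1L]] <- list(units = units, set = s)
  }
  list(cfg = synth_config(
         n_units = 72L, n_days = 8L,
         trials_per_day = c(observational = 0L, conditioning = 10L,
                            inference_test = 12L),
         rest_s = 200, iti_s = 4, tuning_map = tmap,
         tuning_gain = 5, prospective_gain = 2, p_correct = 0.7,
         swr_rate = 0.35, coactivation_sets = co, planted_lag_ms = lags,
         seed = GLOBAL_SEED),
       tuples = tp)
}

# Reload the session written by 01_simulate.R, normalizing the JSON ground
# truth back to native types.
load_demo <- function() {
  session <- load_session(SESSION_DIR)
  gt <- attr(session, "truth")
  gt$tuning <- vapply(gt$tuning, function(x)
    if (is.null(x) || is.na(x)) NA_character_ else as.character(x), "")
  list(session = session, truth = gt)
}
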