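# Shared fixtures: small synthetic sessions built in code at test time.

small_config <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(
    n_units = 24L, n_days = 2L,
    trials_per_day = c(observational = 0L, conditioning = 8L,
                       inference_test = 8L),
    rest_s = 60, iti_s = 3, tuned_fraction = 1 / 12, seed = seed)
  do.call(synth_config, utils::modifyList(defaults, args))
}

small_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_session(small_config(seed = 42L))
    cache
  }
})

# brute-force recovery oracle: mean-rate contrast per cue window vs rest
brute_rate_contrast <- function(session, cue) {
  tr <- session$trials[session$trials$cue == cue, ]
  w <- as.matrix(tr[, c("onset", "offset")])
  tot_w <- sum(w[, 2L] - w[, 1L])
  spl <- split(session$spikes$time_s,
               factor(session$spikes$unit_id,
                      levels = seq_len(session$meta$n_units)))
  vapply(spl, function(st) {
    n_in <- sum(vapply(seq_len(nrow(w)), function(i)
      sum(st >= w[i, 1L] & st < w[i, 2L]), 1))
    n_in / tot_w - (length(st) - n_in) / (session$meta$t_end - tot_w)
  }, 1)
}
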