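swr_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- list(
        list(units = 1:3, prob = 0.30, days = 1:2, lag_ms = c(5, 2, 0)),
        list(units = 4:5, prob = 0.25, days = 1:2))
      cfg <- small_config(seed = 51L, n_units = 16L, rest_s = 250,
                          swr_rate = 0.3, tuned_fraction = 0,
                          baseline_rate = 1.5, coactivation_sets = co,
                          trials_per_day = c(observational = 0L,
                                             conditioning = 2L,
                                             inference_test = 2L))
      g <- generate_session(cfg)
      cache <<- list(cfg = cfg, g = g,
                     swrs = truth_swr_set(g$truth),
                     part = participation_matrix(truth_swr_set(g$truth),
                                                 g$session))
    }
    cache
  }
})

test_that("planted ripples are detected with high recall and no movement hits", {
  fx <- swr_fixture()
  lfp <- generate_lfp(fx$cfg, fx$g$truth, fx$g$session$epochs)
  det <- detect_swrs(lfp, fx$g$session)
  tr <- fx$g$truth$swr_events
  ov <- vapply(seq_len(nrow(tr)), function(i)
    hippens:::interval_overlap(tr$start[i], tr$end[i],
                               as.matrix(det[, c("start", "end")])) /
      (tr$end[i] - tr$start[i]), 1)
  expect_gte(mean(ov >= 0.5), 0.95)
  # all detections inside immobility epochs
  ep <- as.matrix(fx$g$session$epochs[, c("start", "end")])
  expect_true(all(hippens:::in_any_interval(det$start, ep)))
  expect_true(all(det$peak_sd > 7))
})

test_that("detection is invariant to uniform LFP scaling and kills common mode", {
  fx <- swr_fixture()
  lfp <- generate_lfp(fx$cfg, fx$g$truth, fx$g$session$epochs)
  det1 <- detect_swrs(lfp, fx$g$session)
  lfp2 <- lfp
  lfp2$segments <- lapply(lfp$segments, function(s) {
    s$lfp <- s$lfp * 37; s$ref <- s$ref * 37; s
  })
  det2 <- detect_swrs(lfp2, fx$g$session)
  expect_equal(det1$start, det2$start, tolerance = 1e-12)
  expect_equal(det1$end, det2$end, tolerance = 1e-12)
  # identical detection and reference signal cancels: no events
  lfp3 <- lfp
  lfp3$segments <- lapply(lfp$segments, function(s) { s$ref <- s$lfp; s })
  expect_identical(nrow(detect_swrs(lfp3, fx$g$session)), 0L)
  expect_error(detect_swrs(structure(list(segments = list(), rate = 300),
                                     class = "lfp_trace"), fx$g$session),
               "Nyquist")
})

test_that("coactivation p-hat matches the brute-force formula exactly", {
  fx <- swr_fixture()
  co <- triplet_coactivation(fx$g$session, fx$swrs, fx$part,
                             list(list(units = 1:3, set = 1L)),
                             day_split = list(early = 1L, late = 2L))
  expect_identical(nrow(co), 1L)
  # independent event-by-event oracle
  for (ep in c("early", "late")) {
    d <- if (ep == "early") 1L else 2L
    sel <- fx$swrs$day == d
    n <- 0L
    for (i in which(sel))
      if (all(fx$part[i, 1:3] >= 1L)) n <- n + 1L
    expect_identical(co[[paste0("n_", ep)]], n)
    expect_identical(co[[paste0("N_", ep)]], sum(sel))
    expect_equal(co[[paste0("p_", ep)]],
                 (n / sum(sel)) / co[[paste0("f_", ep)]], tolerance = 1e-15)
  }
  expect_equal(co$p_diff, co$p_late - co$p_early, tolerance = 1e-15)
  # worked arithmetic: n=5, N=50, f=2 -> 0.05
  expect_equal((5 / 50) / 2, 0.05)
})

test_that("doublet in-absence-of-Y count never exceeds the unconditional count", {
  fx <- swr_fixture()
  ds <- list(early = 1L, late = 2L)
  tup <- list(list(units = 4:5, set = 2L))
  any_y <- triplet_coactivation(fx$g$session, fx$swrs, fx$part, tup, ds)
  no_y <- triplet_coactivation(fx$g$session, fx$swrs, fx$part, tup, ds,
                               exclude_units = 1:3)
  expect_lte(no_y$n_early, any_y$n_early)
  expect_lte(no_y$n_late, any_y$n_late)
  expect_identical(no_y$N_early, any_y$N_early)
})

test_that("set-by-day ANOVA finds a planted set-1-only increase", {
  # planted p_diff shift for set 1 only, across simulated tuples
  set.seed(61)
  mk <- function(set, shift) data.frame(
    label = "t", set = set, n_early = 1L, N_early = 10L, f_early = 1,
    p_early = rnorm(1, 0.05, 0.01),
    n_late = 1L, N_late = 10L, f_late = 1,
    p_late = rnorm(1, 0.05 + shift, 0.01))
  res <- do.call(rbind, c(lapply(1:40, function(i) mk(1L, 0.05)),
                          lapply(1:40, function(i) mk(2L, 0))))
  res$p_diff <- res$p_late - res$p_early
  class(res) <- c("coactivation_result", "data.frame")
  cb <- coactivation_bootstrap(res, n_boot = 1000, seed = 2)
  expect_lt(cb$anova$p, 0.001)
  expect_gt(cb$effects$set1$ci_low, 0)
  expect_lt(cb$effects$set2$ci_low, 0)
  expect_gt(cb$effects$set2$ci_high, 0)
  # a common additive shift in every cell leaves the interaction null
  res2 <- res
  res2$p_late <- res2$p_early + 0.03 + rnorm(80, 0, 0.01)
  res2$p_diff <- res2$p_late - res2$p_early
  cb2 <- coactivation_bootstrap(res2, n_boot = 1000, seed = 3)
  expect_gt(cb2$anova$p, 0.01)
  # empty design cell errors with the cell named
  expect_error(coactivation_bootstrap(res[res$set == 1L, ]), "set 2")
})

test_that("X-shuffle control preserves counts and flags maximal dependence", {
  fx <- swr_fixture()
  part <- fx$part
  ds <- list(early = 1L, late = 2L)
  sh <- swr_shuffle_control(part, fx$swrs, x_unit = 1L, z_unit = 3L,
                            day_split = ds, n_perm = 500, seed = 3)
  expect_false(sh$degenerate)
  expect_length(sh$null, 500L)
  # identical X and Z participation with an early-to-late increase sits in
  # the extreme tail of the independence null
  set.seed(99)
  n_ev <- 200L
  days <- rep(1:2, each = 100L)
  x <- c(rbinom(100, 1, 0.10), rbinom(100, 1, 0.60))
  part2 <- cbind(x, x)
  swrs2 <- data.frame(event_id = 1:n_ev, day = days, start = 1:n_ev,
                      end = 1:n_ev + 0.08, context = "awake_rest")
  sh2 <- swr_shuffle_control(part2, swrs2, 1L, 2L,
                             day_split = list(early = 1L, late = 2L),
                             n_perm = 1000, seed = 4)
  expect_lte(sh2$p, 0.01)
})

test_that("calibrated shuffle control under independent participation", {
  set.seed(71)
  hits <- 0L
  for (i in 1:40) {
    n_ev <- 120L
    days <- rep(1:2, each = 60L)
    part <- cbind(rbinom(n_ev, 1, 0.3), rbinom(n_ev, 1, 0.3))
    swrs <- data.frame(event_id = 1:n_ev, day = days, start = 1:n_ev,
                       end = 1:n_ev + 0.08, context = "awake_rest")
    sh <- swr_shuffle_control(part, swrs, 1L, 2L,
                              day_split = list(early = 1L, late = 2L),
                              n_perm = 400, seed = i)
    if (sh$p < 0.05) hits <- hits + 1L
  }
  expect_lte(hits, 7L)  # ~ binomial(40, 0.05) upper tail
})

test_that("co-firing correlations: identity, independence, planted dependence", {
  fx <- swr_fixture()
  part <- fx$part
  r <- swr_cofire_correlation(part)
  expect_true(is.na(r[1L, 1L]))
  # planted coactivation pair correlates positively
  expect_gt(r[4L, 5L], 0.2)
  # identical count vectors give r = 1
  part2 <- cbind(part, part[, 4L])
  r2 <- swr_cofire_correlation(part2)
  expect_equal(r2[4L, ncol(part2)], 1)
  # independent Poisson counts average near zero
  set.seed(81)
  pp <- matrix(rpois(200 * 20, 0.5), 200, 20)
  rr <- swr_cofire_correlation(pp)
  expect_lt(abs(mean(rr[upper.tri(rr)], na.rm = TRUE)), 0.03)
  expect_warning(swr_cofire_correlation(part[1:5, ]), "unstable")
})

test_that("first-spike order: planted lead, tie dropping, time-reversal antisymmetry", {
  fx <- swr_fixture()
  # planted lag: unit 3 (Z role, lag 0) leads unit 1 (X role, +5 ms)
  fso <- first_spike_order(fx$swrs, fx$g$session,
                           data.frame(x = 1L, z = 3L))
  expect_lt(fso$per_pair$median_dt, 0)
  # hand-built session, one spike per unit per ripple: exact antisymmetry
  ev <- data.frame(event_id = 1:3, day = 1L, start = c(10, 20, 30),
                   end = c(10.1, 20.1, 30.1), context = "awake_rest")
  spk <- data.frame(unit_id = rep(1:2, each = 3),
                    time_s = c(10.05, 20.02, 30.04,    # X
                               10.03, 20.06, 30.01))   # Z
  mini <- structure(list(spikes = spk[order(spk$unit_id, spk$time_s), ],
                         meta = list(n_units = 2L)), class = "session_data")
  f1 <- first_spike_order(ev, mini, data.frame(x = 1L, z = 2L))
  expect_equal(f1$per_pair$median_dt, median(c(-0.02, 0.04, -0.03)),
               tolerance = 1e-9)
  t_end <- 50
  rev_spk <- spk; rev_spk$time_s <- t_end - spk$time_s
  mini_r <- structure(list(spikes = rev_spk[order(rev_spk$unit_id,
                                                  rev_spk$time_s), ],
                           meta = list(n_units = 2L)),
                      class = "session_data")
  ev_r <- data.frame(event_id = 1:3, day = 1L, start = t_end - ev$end,
                     end = t_end - ev$start + 1e-4, context = "awake_rest")
  f2 <- first_spike_order(ev_r, mini_r, data.frame(x = 1L, z = 2L))
  expect_equal(f2$per_pair$median_dt, -f1$per_pair$median_dt,
               tolerance = 1e-9)
  # simultaneous first spikes are dropped and logged
  spk3 <- rbind(spk, data.frame(unit_id = c(1L, 2L), time_s = c(40.02, 40.02)))
  ev3 <- rbind(ev, data.frame(event_id = 4L, day = 1L, start = 40,
                              end = 40.1, context = "awake_rest"))
  mini3 <- structure(list(spikes = spk3[order(spk3$unit_id, spk3$time_s), ],
                          meta = list(n_units = 2L)), class = "session_data")
  f3 <- first_spike_order(ev3, mini3, data.frame(x = 1L, z = 2L))
  expect_identical(f3$n_ties_dropped, 1L)
  expect_identical(f3$per_pair$n_events, 3L)
})

test_that("first-spike fraction is calibrated under independent timing", {
  set.seed(91)
  ps <- vapply(1:60, function(i) {
    n_ev <- 40L
    ev <- data.frame(event_id = 1:n_ev, day = 1L, start = seq_len(n_ev) * 10,
                     end = seq_len(n_ev) * 10 + 0.1, context = "awake_rest")
    n_pairs <- 16L
    spk <- do.call(rbind, lapply(seq_len(2L * n_pairs), function(u)
      data.frame(unit_id = u, time_s = ev$start + runif(n_ev, 0, 0.1))))
    mini <- structure(list(spikes = spk[order(spk$unit_id, spk$time_s), ],
                           meta = list(n_units = 2L * n_pairs)),
                      class = "session_data")
    fso <- first_spike_order(ev, mini,
                             data.frame(x = seq(1, 2 * n_pairs, 2),
                                        z = seq(2, 2 * n_pairs, 2)))
    fso$binom_p
  }, 1)
  expect_lte(mean(ps < 0.05), 0.12)  # ~alpha with binomial discreteness
})
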