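one_window <- function(len = 100) matrix(c(0, len), 1)

test_that("shifted-copy train gives a single correlogram peak at the lag", {
  set.seed(2)
  trig <- sort(runif(400, 1, 99))
  targ <- sort(trig + 0.0072)  # +7.2 ms
  cc <- cross_correlogram(trig, targ, one_window())
  expect_false(cc$empty)
  expect_equal(cc$lag_ms[which.max(cc$counts)], 7.5)  # bin [7, 8)
  expect_gte(max(cc$counts), 400L)  # every trigger plus chance coincidences
  # no-trigger input is flagged empty
  expect_true(cross_correlogram(numeric(0), targ, one_window())$empty)
})

test_that("correlogram count symmetry: ccg(a,b)[+t] = ccg(b,a)[-t]", {
  set.seed(4)
  a <- sort(runif(300, 0, 50)); b <- sort(runif(300, 0, 50))
  ab <- cross_correlogram(a, b, one_window(50))
  ba <- cross_correlogram(b, a, one_window(50))
  expect_identical(ab$counts, rev(ba$counts))
})

test_that("independent Poisson trains give a flat correlogram", {
  set.seed(6)
  trig <- sort(runif(2000, 0, 500)); targ <- sort(runif(2000, 0, 500))
  cc <- cross_correlogram(trig, targ, one_window(500))
  lam <- mean(cc$counts)
  band <- qpois(c(0.0005, 0.9995), lam)  # 99.9% band, 200 bins
  expect_gte(min(cc$counts), band[1L])
  expect_lte(max(cc$counts), band[2L])
})

test_that("STA matches a brute-force double loop exactly on small sessions", {
  set.seed(8)
  win <- rbind(c(0, 30), c(40, 60))
  trig <- sort(runif(120, 0, 60)); targ <- sort(runif(300, 0, 60))
  sta <- spike_triggered_average(trig, targ, win)
  # brute force: all spike pairs, same-window, per-bin trigger normalizer
  edges <- seq(-100, 100)
  counts <- integer(200); contrib <- integer(200)
  for (w in seq_len(nrow(win))) {
    tg <- trig[trig >= win[w, 1] & trig < win[w, 2]]
    ta <- targ[targ >= win[w, 1] & targ < win[w, 2]]
    for (t0 in tg) {
      for (b in 1:200) {
        lo <- t0 + edges[b] / 1000; hi <- t0 + edges[b + 1] / 1000
        if (lo >= win[w, 1] && hi <= win[w, 2]) {
          contrib[b] <- contrib[b] + 1L
          counts[b] <- counts[b] + sum(ta >= lo & ta < hi)
        }
      }
    }
  }
  rate <- counts / (contrib * 1e-3)
  z <- (rate - mean(rate)) / sd(rate)
  expect_equal(sta$z, z, tolerance = 1e-12)
  expect_equal(sta$n_trigger, length(trig[trig < 30 | trig >= 40]))
})

test_that("sub-threshold pairs are excluded with an explicit record", {
  trig <- sort(runif(50, 0, 100))
  targ <- sort(runif(10, 0, 100))  # far fewer than 20 in-window spikes
  sta <- spike_triggered_average(trig, targ, one_window())
  expect_false(sta$included)
  expect_lt(sta$n_target, 20)
  expect_error(sta_asymmetry(list(sta, sta)), "included")
})

test_that("fixed-lag firing produces post-trigger Z and sign-flips on reversal", {
  set.seed(10)
  trig <- sort(runif(300, 1, 99))
  targ <- sort(trig + 0.0033)
  sta <- spike_triggered_average(trig, targ, one_window())
  expect_gt(max(sta$z[sta$lag_ms > 0]), 5)
  expect_true(all(sta$z[sta$lag_ms > 0][4] > sta$z[sta$lag_ms < 0]))
  a <- sta_asymmetry(list(sta, sta), n_boot = 1000, seed = 1)
  expect_gt(a$effect$estimate, 0)
  # time reversal flips the asymmetry exactly
  rev_trig <- sort(100 - trig); rev_targ <- sort(100 - targ)
  sta_r <- spike_triggered_average(rev_trig, rev_targ, one_window())
  a_r <- sta_asymmetry(list(sta_r, sta_r), n_boot = 1000, seed = 1)
  expect_equal(a_r$effect$estimate, -a$effect$estimate, tolerance = 1e-9)
})

test_that("symmetric jitter gives near-zero asymmetry; display smoothing works", {
  set.seed(12)
  trig <- sort(runif(3000, 1, 999))
  targ <- sort(trig + runif(3000, -0.02, 0.02))
  sta <- spike_triggered_average(trig, targ, one_window(1000))
  after <- sta$lag_ms > 0
  expect_lt(abs(mean(sta$z[after]) - mean(sta$z[!after])), 0.3)
  sm <- sta_smooth(sta)
  expect_length(sm, 200L)
  expect_true(anyNA(sm))  # edge bins undefined under centred smoothing
})

test_that("planted ensemble lags are recovered within a millisecond", {
  lagdf <- data.frame(trigger = c(1, 2, 3), target = c(7, 8, 9),
                      lag_ms = c(7, 15, 23), prob = 0.35)
  cfg <- small_config(seed = 29L, n_units = 12L, tuned_fraction = 0,
                      planted_lag_ms = lagdf, rest_s = 0,
                      trials_per_day = c(observational = 0L,
                                         conditioning = 2L,
                                         inference_test = 20L))
  g <- generate_session(cfg)
  s <- g$session
  x_win <- as.matrix(s$trials[s$trials$cue %in% c("X1", "X2"),
                              c("onset", "offset")])
  spl <- split(s$spikes$time_s, factor(s$spikes$unit_id, levels = 1:12))
  for (i in 1:3) {
    cc <- cross_correlogram(spl[[lagdf$trigger[i]]], spl[[lagdf$target[i]]],
                            x_win)
    peak <- cc$lag_ms[which.max(cc$counts)]
    expect_lt(abs(peak - lagdf$lag_ms[i]), 1 + 1e-9)
  }
})
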