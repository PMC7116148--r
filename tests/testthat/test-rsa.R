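pat <- function(m, conds, features = NULL) {
  m <- as.matrix(m)
  colnames(m) <- conds
  rownames(m) <- features %||% as.character(seq_len(nrow(m)))
  class(m) <- c("pattern_matrix", class(m))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cross RSM agrees with a per-pair correlation oracle to 1e-12", {
  set.seed(5)
  te <- pat(matrix(rnorm(25), 5), paste0("X", 1:5))
  tr <- pat(matrix(rnorm(25), 5), paste0("Y", 1:5))
  rsm <- cross_rsm(te, tr, assoc = setNames(paste0("Y", 1:5), paste0("X", 1:5)))
  for (i in 1:5) for (j in 1:5)
    expect_equal(rsm$r[i, j], cor(te[, i], tr[, j]), tolerance = 1e-12)
  expect_false(isSymmetric(rsm$r))
})

test_that("worked 2x2 example: identical/opposite patterns give statistic 2", {
  te <- pat(cbind(c(1, 0, 1, 0), c(0, 1, 0, 1)), c("X1", "X2"))
  tr <- pat(cbind(c(1, 0, 1, 0), c(0, 1, 0, 1)), c("Y1", "Y2"))
  rsm <- cross_rsm(te, tr)
  expect_equal(rsm$r[1, 1], 1); expect_equal(rsm$r[1, 2], -1)
  expect_equal(within_minus_between(rsm), 2)
  # matched-condition diagonal is 1 when test == train
  expect_equal(unname(diag(cross_rsm(te, pat(unclass(te), c("Y1", "Y2")))$r)),
               c(1, 1))
  # all cells equal -> 0; constant shift invariance
  rsm0 <- rsm; rsm0$r[] <- 0.4
  expect_equal(within_minus_between(rsm0), 0)
  rsm1 <- rsm; rsm1$r <- rsm1$r * 0.3  # keep within [-1, 1]
  expect_equal(within_minus_between(rsm1), 0.3 * 2)
})

test_that("orthogonal random patterns give near-zero correlations", {
  set.seed(11)
  te <- pat(matrix(rnorm(4000), 1000), c("X1", "X2", "X3", "X4"))
  tr <- pat(matrix(rnorm(4000), 1000), c("Y1", "Y2", "Y3", "Y4"))
  rsm <- cross_rsm(te, tr, assoc = setNames(paste0("Y", 1:4), paste0("X", 1:4)))
  expect_lt(max(abs(rsm$r)), 0.11)
  expect_error(cross_rsm(te[1:2, ], tr[1:2, ]), "3")
})

test_that("permutation null: trivial cases and seed stability bound", {
  set.seed(3)
  mk_rsm <- function() {
    te <- pat(matrix(rnorm(40), 20), c("X1", "X2"))
    tr <- pat(matrix(rnorm(40), 20), c("Y1", "Y2"))
    cross_rsm(te, tr)
  }
  rsms <- replicate(12, mk_rsm(), simplify = FALSE)
  p1 <- permutation_null(rsms, n_perm = 2000, seed = 1)
  p2 <- permutation_null(rsms, n_perm = 2000, seed = 2)
  expect_lt(abs(p1$p - p2$p), 3 * sqrt(p1$p * (1 - p1$p) / 2000) + 0.01)
  # 2 labels, single RSM: only 2 distinct permutations exist
  one <- permutation_null(rsms[1], n_perm = 500, seed = 1)
  expect_lte(length(unique(round(one$null, 12))), 2L)
  # single 2x2 RSM: null has two atoms, the favorable one lands near 0.5
  sym <- rsms[[1]]; sym$r[] <- c(0.3, 0.2, 0.2, 0.3)
  ps <- permutation_null(list(sym), n_perm = 1000, seed = 4)
  expect_gt(ps$p, 0.4); expect_lt(ps$p, 0.6)
  expect_warning(permutation_null(rsms, n_perm = 50, seed = 1), "n_perm")
})

test_that("model-RSM regression recovers planted mixtures", {
  A <- matrix(c(1, 0, 0, 1), 2, 2)   # association model (diagonal)
  C <- matrix(c(1, 1, 0, 0), 2, 2)   # orthogonal-after-centering model
  mk <- function(r) structure(list(r = r, within = A > 0), class = "rsm")
  # RSM equal to model A: positive A weight, zero weight on orthogonal C
  w <- rsm_model_regression(mk(0.5 * A), list(a = A, c = C), fisher = FALSE)
  expect_gt(w["a"], 0)
  expect_equal(unname(w["c"]), 0, tolerance = 1e-9)
  # equal mixture of the two models: equal weights
  w2 <- rsm_model_regression(mk(0.3 * A + 0.3 * C), list(a = A, c = C),
                             fisher = FALSE)
  expect_equal(unname(w2["a"]), unname(w2["c"]), tolerance = 1e-9)
  expect_error(rsm_model_regression(mk(0.5 * A), list(a = A, a2 = A * 2)),
               "[Cc]ollinear")
})

test_that("Wilcoxon group inference: calibration, power, and edge cases", {
  expect_identical(group_inference(rep(0, 8))$p, 1)
  # all positive values: minimal exact p for that n
  n <- 10L
  expect_equal(group_inference(seq_len(n) / 10)$p, 2^(-n), tolerance = 1e-12)
  # rejection rate near alpha under symmetric null
  set.seed(21)
  rej <- mean(vapply(1:400, function(i)
    group_inference(rnorm(18))$p < 0.05, TRUE))
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
  # power at delta = 1 sigma, n = 18
  pow <- mean(vapply(1:200, function(i)
    group_inference(rnorm(18, 1))$p < 0.05, TRUE))
  expect_gt(pow, 0.9)
})

test_that("planted prospective code yields the correct-only RSA pattern", {
  cfg <- small_config(seed = 43L, n_units = 48L, tuned_fraction = 1 / 12,
                      prospective_gain = 2, p_correct = 0.6, n_days = 4L,
                      trials_per_day = c(observational = 0L,
                                         conditioning = 10L,
                                         inference_test = 12L))
  g <- generate_session(cfg)
  br <- bin_and_zscore(g$session)
  wmb <- function(split) {
    vapply(1:4, function(d) {
      te <- population_vectors(br, c("X1", "X2"), split = split, days = d)
      tr <- population_vectors(br, c("Y1", "Y2"), days = d)
      within_minus_between(cross_rsm(te, tr))
    }, 1)
  }
  wc <- wmb("correct"); wi <- wmb("incorrect")
  expect_gt(mean(wc), 0.15)
  expect_lt(abs(mean(wi)), 0.15)
  expect_lt(suppressWarnings(group_inference(wc))$p, 0.07)
})

test_that("population vectors: averaging is idempotent and trial-equal-weighted", {
  g <- small_session()
  br <- bin_and_zscore(g$session)
  pv <- population_vectors(br, c("X1", "X2"))
  expect_true(all(is.finite(pv)))
  expect_identical(colnames(pv), c("X1", "X2"))
  # restricting to one trial reproduces that trial's mean
  b1 <- br$bins$trial_id[br$bins$included & br$bins$cue == "X1"][1L]
  sel <- br$bins$included & br$bins$trial_id == b1
  units <- setdiff(seq_len(nrow(br$z)), br$zero_var)
  manual <- rowMeans(br$z[units, sel, drop = FALSE])
  # single-trial condition via exclude: keep only this trial's window
  other <- br$bins$t0[br$bins$cue == "X1" & br$bins$trial_id != b1]
  excl <- cbind(other, other + br$bin_s)
  pv1 <- population_vectors(br, "X1", exclude_intervals = excl)
  expect_equal(unname(pv1[, "X1"]), unname(manual), tolerance = 1e-12)
})
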