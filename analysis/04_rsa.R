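#!/usr/bin/env Rscript
# Cross-stage representational similarity: per-day RSMs between auditory
# cues at inference (decision-point filtered, split by performance) and
# visual cues at conditioning; within-minus-between statistic; Wilcoxon
# and label-permutation group inference; model-RSM regression.

source("analysis/00_config.R")
dm <- load_demo()

br <- bin_and_zscore(dm$session)
days <- sort(unique(dm$session$trials$day))
swr_int <- as.matrix(dm$truth$swr_events[, c("start", "end")])

mk <- function(split) lapply(days, function(d) {
  te <- population_vectors(br, c("X1", "X2"), split = split, days = d,
                           exclude_intervals = swr_int)
  tr <- population_vectors(br, c("Y1", "Y2"), days = d,
                           exclude_intervals = swr_int)
  cross_rsm(te, tr)
})
rc <- mk("correct"); ri <- mk("incorrect")
wmb_c <- vapply(rc, within_minus_between, 1)
wmb_i <- vapply(ri, within_minus_between, 1)
write.csv(data.frame(day = days, wmb_correct = wmb_c, wmb_incorrect = wmb_i),
          file.path(RESULTS_DIR, "04_rsa_within_minus_between.csv"),
          row.names = FALSE)

gc_ <- group_inference(wmb_c); gi_ <- group_inference(wmb_i)
pc <- permutation_null(rc, n_perm = 10000L,
                       seed = derive_seed(GLOBAL_SEED, 41L))
pi_ <- permutation_null(ri, n_perm = 10000L,
                        seed = derive_seed(GLOBAL_SEED, 42L))
cat(sprintf("correct trials:   within-between %.3f, Wilcoxon p %.4g, permutation p %.4g\n",
            mean(wmb_c), gc_$p, pc$p))
cat(sprintf("incorrect trials: within-between %.3f, Wilcoxon p %.4g, permutation p %.4g\n",
            mean(wmb_i), gi_$p, pi_$p))

# model-RSM regression: association model vs a set-1-preference model
assoc_model <- diag(2)
value_model <- matrix(c(1, 1, 0, 0), 2, 2)  # rows: X1, X2
wts <- t(vapply(rc, function(rs)
  rsm_model_regression(rs, list(association = assoc_model,
                                value = value_model)), numeric(2)))
cat(sprintf("model regression (correct): association %.3f (Wilcoxon p %.3g), value %.3f (p %.3g)\n",
            mean(wts[, 1]), group_inference(wts[, 1])$p,
            mean(wts[, 2]), group_inference(wts[, 2])$p))

jsonlite::write_json(
  list(wmb_correct = mean(wmb_c), wmb_incorrect = mean(wmb_i),
       wilcoxon_p_correct = gc_$p, wilcoxon_p_incorrect = gi_$p,
       permutation_p_correct = pc$p, permutation_p_incorrect = pi_$p,
       model_weights = list(association = mean(wts[, 1]),
                            value = mean(wts[, 2]))),
  file.path(RESULTS_DIR, "04_rsa_inference.json"),
  auto_unbox = TRUE, digits = NA)
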