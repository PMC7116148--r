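# Representational similarity: population vectors, cross-stage RSMs,
# within-minus-between statistics, model-RSM regression, permutation and
# Wilcoxon group inference. Modality-agnostic: features may be units or
# any feature-by-condition pattern.

#' Condition population vectors from binned rates
#'
#' For each requested condition (cue, optionally restricted to correct or
#' incorrect inference trials and to a subset of days), averages each
#' unit's decision-point-included Z-scored rate within trial and then
#' across trials (equal trial weighting). Units flagged as zero-variance
#' are dropped; conditions with no included bins are dropped with a
#' message.
#'
#' @param br a `binned_rates`.
#' @param cues condition cue ids (columns of the result).
#' @param split `"all"`, `"correct"` or `"incorrect"` (inference trials).
#' @param days optional day subset.
#' @param exclude_intervals optional 2-column matrix of time intervals
#'   (e.g. SWR events) whose bins are excluded.
#' @return a `pattern_matrix`: numeric matrix features x conditions with
#'   `attr(, "n_trials")` per condition.
#' @export
population_vectors <- function(br, cues, split = c("all", "correct", "incorrect"),
                               days = NULL, exclude_intervals = NULL) {
  split <- match.arg(split)
  bins <- br$bins
  keep <- bins$included & bins$cue %in% cues
  if (!is.null(days)) keep <- keep & bins$day %in% days
  if (split != "all")
    keep <- keep & !is.na(bins$correct) &
      (bins$correct == (split == "correct"))
  if (!is.null(exclude_intervals) && nrow(exclude_intervals))
    keep <- keep & !in_any_interval(bins$t0, exclude_intervals) &
      !in_any_interval(bins$t1 - 1e-9, exclude_intervals)
  units <- setdiff(seq_len(nrow(br$z)), br$zero_var)
  cols <- list(); n_tr <- integer(0)
  for (cu in cues) {
    sel <- keep & bins$cue == cu
    if (!any(sel)) {
      message("condition dropped (no included bins): ", cu)
      next
    }
    f <- factor(bins$trial_id[sel])
    per_trial <- apply(br$z[units, sel, drop = FALSE], 1L,
                       function(r) tapply(r, f, mean))
    v <- if (is.matrix(per_trial)) colMeans(per_trial) else per_trial
    cols[[cu]] <- v
    n_tr <- c(n_tr, nlevels(f))
  }
  if (!length(cols)) stop("no conditions with included bins")
  m <- do.call(cbind, cols)
  rownames(m) <- as.character(units)
  attr(m, "n_trials") <- setNames(n_tr, names(cols))
  class(m) <- c("pattern_matrix", class(m))
  m
}

#' Cross-stage representational similarity matrix
#'
#' Pearson correlation between every test-stage and every training-stage
#' condition pattern. The matrix is not symmetric in general: rows index
#' test conditions, columns training conditions. The association map marks
#' "within" cells (the learned pairing, e.g. X1-Y1, X2-Y2) versus
#' "between" cells.
#'
#' @param test,train `pattern_matrix` objects with identical feature
#'   ordering (test: e.g. auditory cues at inference; train: visual or
#'   outcome cues at conditioning).
#' @param assoc named character vector mapping each test condition to its
#'   associated training condition; default pairs conditions sharing the
#'   set digit (X1 -> Y1/Z1).
#' @return an `rsm`: list with `r` (test x train correlation matrix) and
#'   `within` (logical matrix marking associated cells).
#' @export
cross_rsm <- function(test, train, assoc = NULL) {
  if (!identical(rownames(test), rownames(train)))
    stop("test and train matrices must share feature ordering")
  if (nrow(test) < 3L)
    stop("fewer than 3 shared features; correlations undefined")
  r <- cor(as.matrix(test), as.matrix(train))
  if (is.null(assoc)) {
    assoc <- setNames(colnames(train)[match(substr(colnames(test), 2L, 2L),
                                            substr(colnames(train), 2L, 2L))],
                      colnames(test))
  }
  within <- matrix(FALSE, nrow(r), ncol(r), dimnames = dimnames(r))
  for (tc in rownames(r)) {
    if (!is.na(assoc[tc]) && assoc[tc] %in% colnames(r))
      within[tc, assoc[tc]] <- TRUE
  }
  structure(list(r = r, within = within, assoc = assoc), class = "rsm")
}

#' Within-minus-between association statistic
#'
#' Mean correlation over "within" (associated) cells minus the mean over
#' "between" cells. Positive values indicate that test-stage activity
#' resembles the representation of the associated training-stage
#' condition more than the non-associated ones.
#'
#' @param rsm an `rsm`.
#' @param fisher apply the Fisher z-transform to correlations before
#'   averaging.
#' @return the statistic (scalar).
#' @export
within_minus_between <- function(rsm, fisher = FALSE) {
  r <- rsm$r
  if (fisher) r <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  mean(r[rsm$within]) - mean(r[!rsm$within])
}

#' Permutation null for a group-level RSM statistic
#'
#' The observed group statistic is the mean of `stat_fn` over the per-day
#' (or per-subject) RSMs. The null is built by permuting the identity of
#' the test-stage conditions (matrix rows) within each day independently
#' on each iteration and recomputing the group mean; training-stage labels
#' stay fixed. One-sided add-one p-value
#' (1 + #\{null >= observed\}) / (1 + n_perm).
#'
#' @param rsm_per_day list of `rsm` objects.
#' @param n_perm number of permutations (default 10000; < 100 warns).
#' @param seed integer seed.
#' @param stat_fn statistic, default [within_minus_between()].
#' @param ... passed to `stat_fn`.
#' @return a `perm_test`: `observed`, `p`, `null`, `n_perm`, `seed`.
#' @export
permutation_null <- function(rsm_per_day, n_perm = 10000L, seed = 1L,
                             stat_fn = within_minus_between, ...) {
  if (n_perm < 100L) warning("n_perm < 100 gives coarse p-value resolution")
  n_test <- max(vapply(rsm_per_day, function(rs) nrow(rs$r), 1L))
  if (n_test < 2L) stop("need at least 2 permutable test labels")
  observed <- mean(vapply(rsm_per_day, stat_fn, 1, ...))
  set.seed(as.integer(seed))
  # enumerate each day's row permutations once (days may differ in test
  # conditions, e.g. a split with a dropped condition); each iteration
  # indexes into the per-day stat table
  n_days <- length(rsm_per_day)
  stat_tab <- lapply(rsm_per_day, function(rs) {
    perms <- all_permutations(nrow(rs$r))
    vapply(seq_len(nrow(perms)), function(k) {
      rs2 <- rs
      rs2$r <- rs$r[perms[k, ], , drop = FALSE]
      stat_fn(rs2, ...)
    }, 1)
  })
  null_mat <- vapply(stat_tab, function(tab)
    tab[sample.int(length(tab), n_perm, replace = TRUE)], numeric(n_perm))
  null <- rowMeans(matrix(null_mat, nrow = n_perm))
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  structure(list(observed = observed, p = p, null = null,
                 n_perm = n_perm, seed = seed), class = "perm_test")
}

all_permutations <- function(n) {
  if (n > 6L) stop("permutation enumeration limited to 6 labels")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (pos in seq_len(n)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                            sub[, seq.int(pos, n - 1L)[seq_len(n - pos)],
                                drop = FALSE]))
  }
  unname(out)
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("observed %.4g, one-sided permutation p = %.4g (%d permutations)\n",
              x$observed, x$p, x$n_perm))
  invisible(x)
}

#' Multiple regression of an RSM on model RSMs
#'
#' Vectorizes the RSM cells, Z-scores them, and regresses them on the
#' vectorized model matrices (e.g. an association model conditional on the
#' intermediary cue versus an unconditional one, or value-dependent versus
#' value-independent pairings). Correlations are Fisher-transformed first
#' by default (variance stabilization).
#'
#' @param rsm an `rsm`.
#' @param models named list of numeric model matrices, same dimension as
#'   `rsm$r`.
#' @param fisher Fisher-transform correlations before regression.
#' @return named coefficient vector, one weight per model.
#' @export
rsm_model_regression <- function(rsm, models, fisher = TRUE) {
  y <- as.numeric(rsm$r)
  if (fisher) y <- atanh(pmin(pmax(y, -1 + 1e-12), 1 - 1e-12))
  y <- as.numeric(scale(y))
  X <- vapply(models, function(m) {
    stopifnot(all(dim(m) == dim(rsm$r)))
    as.numeric(m)
  }, numeric(length(y)))
  Xc <- cbind(1, X)
  kap <- kappa(Xc, exact = TRUE)
  if (kap > 1e8)
    stop(sprintf("collinear model RSMs (condition number %.3g)", kap))
  fit <- lm.fit(Xc, y)
  setNames(fit$coefficients[-1L], names(models))
}

#' Group-level one-sided Wilcoxon signed-rank test
#'
#' Tests whether per-day (or per-subject) statistics are shifted above
#' zero. Exact for n <= 25 without ties or zeros, normal approximation
#' otherwise.
#'
#' @param per_day_stats numeric vector.
#' @param alternative direction, default `"greater"`.
#' @return list `statistic` (V), `p`, `n`, `all_zero` flag.
#' @export
group_inference <- function(per_day_stats, alternative = "greater") {
  n <- length(per_day_stats)
  if (n < 5L) warning("fewer than 5 observations; signed-rank test unstable")
  if (all(per_day_stats == 0))
    return(list(statistic = NA_real_, p = 1, n = n, all_zero = TRUE))
  exact <- n <= 25L && !any(per_day_stats == 0) &&
    !any(duplicated(abs(per_day_stats)))
  wt <- suppressWarnings(
    wilcox.test(per_day_stats, mu = 0, alternative = alternative,
                exact = exact))
  list(statistic = unname(wt$statistic), p = wt$p.value, n = n,
       all_zero = FALSE)
}
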